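#' Interaction dataset for the motif search
#'
#' Bundle the four evidence tables the potentially-compensated-unit
#' (PCU) search consumes: transcription-factor promoter binding,
#' physical protein-protein interactions with their evidence throughput
#' class, genetic interactions with free-text category labels, and a
#' list of global regulators to exclude. Gene identifiers are
#' case-normalised to uppercase and physical/genetic pairs are treated
#' as unordered.
#'
#' @param tf_binding Data frame with columns `tf`, `target`.
#' @param physical Data frame with columns `gene_a`, `gene_b`,
#'   `throughput` (values `"low"` or `"high"`).
#' @param genetic Data frame with columns `gene_a`, `gene_b`,
#'   `category` (free-text interaction category names).
#' @param global_regulators Character vector of gene ids to exclude.
#' @param overrides Optional data frame with columns `gene_a`,
#'   `gene_b`, `relation` (`"same"` or `"different"`): manual
#'   sign-relation calls that take precedence over the category-based
#'   classification.
#' @return A list of class `"interaction_dataset"`.
#' @export
interaction_dataset <- function(tf_binding = NULL, physical = NULL,
                                genetic = NULL, global_regulators = character(),
                                overrides = NULL) {
  empty <- function(...) tibble::tibble(...)
  norm <- toupper
  tf_binding <- if (is.null(tf_binding)) {
    empty(tf = character(), target = character())
  } else {
    tibble::tibble(tf = norm(as.character(tf_binding$tf)),
                   target = norm(as.character(tf_binding$target)))
  }
  physical <- if (is.null(physical)) {
    empty(gene_a = character(), gene_b = character(),
          throughput = character())
  } else {
    stopifnot(all(physical$throughput %in% c("low", "high")))
    tibble::tibble(gene_a = norm(as.character(physical$gene_a)),
                   gene_b = norm(as.character(physical$gene_b)),
                   throughput = as.character(physical$throughput))
  }
  genetic <- if (is.null(genetic)) {
    empty(gene_a = character(), gene_b = character(), category = character())
  } else {
    tibble::tibble(gene_a = norm(as.character(genetic$gene_a)),
                   gene_b = norm(as.character(genetic$gene_b)),
                   category = as.character(genetic$category))
  }
  overrides <- if (is.null(overrides)) {
    empty(gene_a = character(), gene_b = character(), relation = character())
  } else {
    stopifnot(all(overrides$relation %in% c("same", "different")))
    tibble::tibble(gene_a = norm(as.character(overrides$gene_a)),
                   gene_b = norm(as.character(overrides$gene_b)),
                   relation = as.character(overrides$relation))
  }
  structure(list(
    tf_binding = dplyr::distinct(tf_binding),
    physical = physical, genetic = genetic,
    global_regulators = unique(norm(as.character(global_regulators))),
    overrides = overrides
  ), class = "interaction_dataset")
}

# canonical unordered pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Physical-interaction support for a gene pair
#'
#' A pair of proteins counts as physically interacting when the
#' evidence comprises at least one low-throughput record or at least
#' two high-throughput records (a guard against high-throughput false
#' positives).
#'
#' @param ds An [interaction_dataset()].
#' @param a,b Gene identifiers (vectorised).
#' @return Logical vector.
#' @export
physical_pair_supported <- function(ds, a, b) {
  stopifnot(inherits(ds, "interaction_dataset"))
  a <- toupper(a); b <- toupper(b)
  keys <- pair_key(a, b)
  ph <- ds$physical
  if (nrow(ph) == 0L) return(rep(FALSE, length(keys)))
  pk <- pair_key(ph$gene_a, ph$gene_b)
  low <- table(pk[ph$throughput == "low"])
  high <- table(pk[ph$throughput == "high"])
  n_low <- as.integer(low[keys]); n_low[is.na(n_low)] <- 0L
  n_high <- as.integer(high[keys]); n_high[is.na(n_high)] <- 0L
  n_low >= 1L | n_high >= 2L
}

GENETIC_POSITIVE <- c("synthetic rescue", "positive genetic",
                      "dosage growth defect", "dosage lethality")
GENETIC_NEGATIVE <- c("dosage rescue", "negative genetic",
                      "synthetic growth defect", "synthetic lethality",
                      "synthetic haploinsufficiency")
GENETIC_AMBIGUOUS <- c("phenotypic enhancement", "phenotypic suppression")

#' Classify a genetic-interaction category label
#'
#' Map free-text genetic-interaction category names to sign-evidence
#' classes. Positive interactions (double mutant less severe than
#' either single mutant) indicate components of *different* regulatory
#' signs; negative interactions (double mutant more severe than
#' expected) indicate the *same* sign. Phenotypic
#' enhancement/suppression are too broad to classify automatically.
#'
#' @param category Character vector of category labels
#'   (case-insensitive).
#' @return Character vector with values `"positive"`, `"negative"`,
#'   `"ambiguous"` or `"unrecognized"`.
#' @examples
#' classify_genetic_category(c("synthetic rescue", "dosage rescue"))
#' @export
classify_genetic_category <- function(category) {
  cl <- tolower(trimws(category))
  dplyr::case_when(
    cl %in% GENETIC_POSITIVE ~ "positive",
    cl %in% GENETIC_NEGATIVE ~ "negative",
    cl %in% GENETIC_AMBIGUOUS ~ "ambiguous",
    .default = "unrecognized"
  )
}

#' Regulatory sign relation between two genes
#'
#' Infer whether two regulators carry the same or different regulatory
#' signs from their genetic-interaction evidence: only positive-class
#' evidence gives `"different"`, only negative-class gives `"same"`,
#' both present gives `"conflict"` (a manual override is required), and
#' only ambiguous or no evidence gives `"unknown"`. Entries in the
#' dataset's override table take precedence.
#'
#' @param ds An [interaction_dataset()].
#' @param a,b Gene identifiers (scalars).
#' @return One of `"same"`, `"different"`, `"conflict"`, `"unknown"`.
#' @export
sign_relation <- function(ds, a, b) {
  stopifnot(inherits(ds, "interaction_dataset"))
  a <- toupper(a); b <- toupper(b)
  key <- pair_key(a, b)
  ov <- ds$overrides
  if (nrow(ov) > 0L) {
    hit <- pair_key(ov$gene_a, ov$gene_b) == key
    if (any(hit)) return(ov$relation[which(hit)[1]])
  }
  ge <- ds$genetic
  if (nrow(ge) == 0L) return("unknown")
  rec <- ge[pair_key(ge$gene_a, ge$gene_b) == key, , drop = FALSE]
  if (nrow(rec) == 0L) return("unknown")
  classes <- classify_genetic_category(rec$category)
  has_pos <- any(classes == "positive")
  has_neg <- any(classes == "negative")
  if (has_pos && has_neg) return("conflict")
  if (has_pos) return("different")
  if (has_neg) return("same")
  "unknown"
}

# any genetic record at all for the unordered pair (conditions 3 and 4
# of the PCU definition only require a *reported* genetic interaction)
has_genetic_record <- function(ds, a, b) {
  ge <- ds$genetic
  if (nrow(ge) == 0L) return(rep(FALSE, length(a)))
  pair_key(toupper(a), toupper(b)) %in% pair_key(ge$gene_a, ge$gene_b)
}

#' Enumerate potentially compensated units
#'
#' A potentially compensated unit (PCU) is a transcription factor plus
#' two regulators whose promoters it binds, such that:
#' 1. at least one regulator physically interacts with the TF,
#' 2. each regulator physically interacts with the TF or with the
#'    other regulator,
#' 3. the two regulators share at least one reported genetic
#'    interaction, and
#' 4. at least one regulator has a reported genetic interaction with
#'    the TF.
#'
#' Physical interaction uses the evidence threshold of
#' [physical_pair_supported()]. Global regulators are excluded both as
#' TFs and as regulators, and a TF cannot be a regulator of its own
#' PCU. Output is deterministic: rows are sorted by (tf, regulator1,
#' regulator2) with regulators in lexicographic order.
#'
#' @param ds An [interaction_dataset()].
#' @return A tibble with columns `tf`, `regulator1`, `regulator2`,
#'   `direct_regulator` (`"first"`, `"second"` or `"both"`) and
#'   `sign_relation`.
#' @export
enumerate_pcus <- function(ds) {
  stopifnot(inherits(ds, "interaction_dataset"))
  tb <- ds$tf_binding
  tb <- tb[!(tb$tf %in% ds$global_regulators) &
             !(tb$target %in% ds$global_regulators) &
             tb$tf != tb$target, , drop = FALSE]
  if (nrow(tb) == 0L) return(empty_pcu_table())
  cand <- tb |>
    dplyr::inner_join(tb, by = "tf", suffix = c("1", "2"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$target1 < .data$target2) |>
    dplyr::rename(regulator1 = "target1", regulator2 = "target2") |>
    dplyr::distinct()
  if (nrow(cand) == 0L) return(empty_pcu_table())
  p1 <- physical_pair_supported(ds, cand$tf, cand$regulator1)
  p2 <- physical_pair_supported(ds, cand$tf, cand$regulator2)
  p12 <- physical_pair_supported(ds, cand$regulator1, cand$regulator2)
  g12 <- has_genetic_record(ds, cand$regulator1, cand$regulator2)
  g1 <- has_genetic_record(ds, cand$tf, cand$regulator1)
  g2 <- has_genetic_record(ds, cand$tf, cand$regulator2)
  keep <- (p1 | p2) &              # condition 1
    (p1 | p12) & (p2 | p12) &      # condition 2
    g12 &                          # condition 3
    (g1 | g2)                      # condition 4
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_pcu_table())
  p1 <- p1[keep]; p2 <- p2[keep]
  out <- tibble::tibble(
    tf = cand$tf, regulator1 = cand$regulator1,
    regulator2 = cand$regulator2,
    direct_regulator = dplyr::case_when(
      p1 & p2 ~ "both", p1 ~ "first", .default = "second"
    ),
    sign_relation = purrr::map2_chr(cand$regulator1, cand$regulator2,
                                    function(a, b) sign_relation(ds, a, b))
  )
  dplyr::arrange(out, .data$tf, .data$regulator1, .data$regulator2)
}

empty_pcu_table <- function() {
  tibble::tibble(tf = character(), regulator1 = character(),
                 regulator2 = character(), direct_regulator = character(),
                 sign_relation = character())
}

#' Classify PCUs as compensated or not
#'
#' A PCU matches a dosage-compensation topology when its two regulators
#' have different regulatory signs *and* exactly one of them physically
#' interacts with the TF (the other acting indirectly through the
#' direct one — the sequestration wiring). Same-sign regulators or two
#' direct regulators are non-compensated; unknown or conflicting sign
#' evidence leaves the PCU indeterminate.
#'
#' @param ds An [interaction_dataset()].
#' @param pcus Tibble from [enumerate_pcus()]; defaults to enumerating
#'   from `ds`.
#' @return The input tibble with a `classification` column
#'   (`"compensated"`, `"non_compensated"`, `"indeterminate"`).
#' @export
classify_pcus <- function(ds, pcus = enumerate_pcus(ds)) {
  pcus$classification <- dplyr::case_when(
    pcus$sign_relation == "same" ~ "non_compensated",
    pcus$direct_regulator == "both" ~ "non_compensated",
    pcus$sign_relation == "different" ~ "compensated",
    .default = "indeterminate"
  )
  pcus
}

#' Merge PCUs into larger networks
#'
#' Automated approximation of combining PCUs into gene networks: build
#' the graph whose nodes are the genes appearing in any PCU and whose
#' edges connect genes co-occurring in a PCU, and take connected
#' components. Each component lists its member genes, member PCUs and
#' how many of them are compensated. This replaces the manual merging
#' and literature verification a curator would perform.
#'
#' @param pcus Classified PCU tibble (from [classify_pcus()]).
#' @return A tibble with one row per network: `network_id`, `genes`
#'   (list column), `n_genes`, `n_pcus`, `n_compensated`.
#' @export
merge_pcus <- function(pcus) {
  if (nrow(pcus) == 0L) {
    return(tibble::tibble(network_id = integer(), genes = list(),
                          n_genes = integer(), n_pcus = integer(),
                          n_compensated = integer()))
  }
  edges <- rbind(cbind(pcus$tf, pcus$regulator1),
                 cbind(pcus$tf, pcus$regulator2),
                 cbind(pcus$regulator1, pcus$regulator2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  membership <- comp$membership
  # order components deterministically by their smallest gene id
  first_gene <- vapply(seq_len(comp$no), function(cid) {
    min(names(membership)[membership == cid])
  }, character(1))
  order_map <- match(seq_len(comp$no), order(first_gene))
  pcu_comp <- order_map[membership[pcus$tf]]
  out <- lapply(sort(unique(order_map)), function(cid) {
    genes <- sort(names(membership)[order_map[membership] == cid])
    members <- pcus[pcu_comp == cid, , drop = FALSE]
    tibble::tibble(
      network_id = cid, genes = list(genes), n_genes = length(genes),
      n_pcus = nrow(members),
      n_compensated = sum(members$classification == "compensated")
    )
  })
  dplyr::bind_rows(out)
}

#' Run the full motif scan
#'
#' Enumerate, classify and merge PCUs from an interaction dataset.
#'
#' @param ds An [interaction_dataset()].
#' @return A list of class `"motif_scan"`: `pcus` (classified PCU
#'   tibble) and `networks` (merged-network tibble).
#' @examples
#' scan <- motif_scan(gal_fixture())
#' scan$pcus
#' @export
motif_scan <- function(ds) {
  pcus <- classify_pcus(ds)
  structure(list(pcus = pcus, networks = merge_pcus(pcus)),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("Motif scan:", nrow(x$pcus), "PCU(s),",
      sum(x$pcus$classification == "compensated"), "compensated,",
      nrow(x$networks), "merged network(s)\n")
  invisible(x)
}
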