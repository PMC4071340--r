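#' Configuration for the synthetic interaction-data generator
#'
#' @param n_tfs,n_regulators Pool sizes for transcription factors and
#'   regulators.
#' @param n_planted_compensated,n_planted_noncompensated Numbers of
#'   motifs to plant.
#' @param n_random_binding_edges,n_random_physical,n_random_genetic
#'   Numbers of uniform-random noise records of each kind.
#' @param high_throughput_fraction Fraction of noise physical records
#'   labelled high-throughput.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_tfs = 5, n_regulators = 20,
                         n_planted_compensated = 3,
                         n_planted_noncompensated = 2,
                         n_random_binding_edges = 30,
                         n_random_physical = 30, n_random_genetic = 30,
                         high_throughput_fraction = 0.5, seed = 1L) {
  stopifnot(n_tfs >= 0, n_regulators >= 0,
            n_planted_compensated >= 0, n_planted_noncompensated >= 0,
            n_random_binding_edges >= 0, n_random_physical >= 0,
            n_random_genetic >= 0,
            high_throughput_fraction >= 0, high_throughput_fraction <= 1)
  n_plants <- n_planted_compensated + n_planted_noncompensated
  if (n_plants > n_tfs || 2 * n_plants > n_regulators) {
    stop("pool too small: need one TF and two regulators per planted motif",
         call. = FALSE)
  }
  structure(list(
    n_tfs = n_tfs, n_regulators = n_regulators,
    n_planted_compensated = n_planted_compensated,
    n_planted_noncompensated = n_planted_noncompensated,
    n_random_binding_edges = n_random_binding_edges,
    n_random_physical = n_random_physical,
    n_random_genetic = n_random_genetic,
    high_throughput_fraction = high_throughput_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic interaction dataset with planted motifs
#'
#' Build a seed-controlled interaction dataset in which a known number
#' of compensated and non-compensated motifs are planted, plus
#' configurable uniform-random noise records. Each planted compensated
#' motif instantiates the sequestration wiring: the TF binds both
#' regulator promoters, exactly one regulator has supported physical
#' evidence to the TF, the other connects physically through the first,
#' a positive-class genetic record links the two regulators, and a
#' genetic record links one regulator to the TF. Non-compensated
#' plants either use a negative-class (same-sign) regulator-regulator
#' record or give both regulators direct physical links to the TF.
#'
#' Noise records are drawn uniformly over the gene pool with a
#' rejection step: a record that would change the compensated-PCU set
#' (creating a spurious compensated PCU, or breaking or reclassifying
#' a planted one) is discarded, so the planted truth remains exactly
#' the compensated set. Incidental non-compensated PCUs are allowed.
#'
#' @param cfg A [synth_config()].
#' @return A list: `dataset` (an [interaction_dataset()]) and `truth`
#'   (tibble of planted PCUs with their planted classification).
#' @export
generate_interaction_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, generate_interaction_dataset_impl(cfg))
}

generate_interaction_dataset_impl <- function(cfg) {
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  regs <- sprintf("REG%03d", seq_len(cfg$n_regulators))
  binding <- tibble::tibble(tf = character(), target = character())
  physical <- tibble::tibble(gene_a = character(), gene_b = character(),
                             throughput = character())
  genetic <- tibble::tibble(gene_a = character(), gene_b = character(),
                            category = character())
  truth <- tibble::tibble(tf = character(), regulator1 = character(),
                          regulator2 = character(),
                          planted_class = character())
  n_plants <- cfg$n_planted_compensated + cfg$n_planted_noncompensated
  plant_tfs <- tfs[seq_len(n_plants)]
  plant_regs <- regs[seq_len(2 * n_plants)]
  for (j in seq_len(n_plants)) {
    tf <- plant_tfs[j]
    r <- sort(plant_regs[c(2 * j - 1, 2 * j)])
    compensated <- j <= cfg$n_planted_compensated
    binding <- dplyr::bind_rows(binding,
      tibble::tibble(tf = tf, target = r))
    if (compensated) {
      # one direct regulator, the other linked through it
      physical <- dplyr::bind_rows(physical,
        tibble::tibble(gene_a = c(tf, r[1]), gene_b = c(r[1], r[2]),
                       throughput = "low"))
      genetic <- dplyr::bind_rows(genetic,
        tibble::tibble(gene_a = c(r[1], tf), gene_b = c(r[2], r[1]),
                       category = c("positive genetic", "negative genetic")))
      cls <- "compensated"
    } else if (j %% 2 == 0) {
      # same-sign plant: sequestration wiring but negative-class sign
      physical <- dplyr::bind_rows(physical,
        tibble::tibble(gene_a = c(tf, r[1]), gene_b = c(r[1], r[2]),
                       throughput = "low"))
      genetic <- dplyr::bind_rows(genetic,
        tibble::tibble(gene_a = c(r[1], tf), gene_b = c(r[2], r[1]),
                       category = c("synthetic lethality", "positive genetic")))
      cls <- "non_compensated"
    } else {
      # dual-direct plant: both regulators touch the TF, different signs
      physical <- dplyr::bind_rows(physical,
        tibble::tibble(gene_a = c(tf, tf), gene_b = r,
                       throughput = "low"))
      genetic <- dplyr::bind_rows(genetic,
        tibble::tibble(gene_a = c(r[1], tf), gene_b = c(r[2], r[1]),
                       category = c("positive genetic", "negative genetic")))
      cls <- "non_compensated"
    }
    truth <- dplyr::bind_rows(truth,
      tibble::tibble(tf = tf, regulator1 = r[1], regulator2 = r[2],
                     planted_class = cls))
  }
  compensated_truth_keys <- with(
    truth[truth$planted_class == "compensated", ],
    paste(tf, regulator1, regulator2))

  # a noise record is admissible only if the compensated-PCU set stays
  # exactly the planted truth: it must neither create a spurious
  # compensated PCU nor break or reclassify a planted one
  alters_compensated_set <- function(b, ph, ge) {
    ds_try <- interaction_dataset(b, ph, ge)
    pcus <- classify_pcus(ds_try)
    comp <- pcus[pcus$classification == "compensated", , drop = FALSE]
    keys <- paste(comp$tf, comp$regulator1, comp$regulator2)
    !setequal(keys, compensated_truth_keys)
  }

  genes <- c(tfs, regs)
  categories <- c(GENETIC_POSITIVE, GENETIC_NEGATIVE, GENETIC_AMBIGUOUS)
  add_noise <- function(n, make_record, bind_to) {
    added <- 0L; guard <- 0L
    while (added < n && guard < 50L * max(n, 1L)) {
      guard <- guard + 1L
      rec <- make_record()
      trial <- switch(bind_to,
        binding = list(dplyr::bind_rows(binding, rec), physical, genetic),
        physical = list(binding, dplyr::bind_rows(physical, rec), genetic),
        genetic = list(binding, physical, dplyr::bind_rows(genetic, rec))
      )
      if (!alters_compensated_set(trial[[1]], trial[[2]], trial[[3]])) {
        binding <<- trial[[1]]; physical <<- trial[[2]]
        genetic <<- trial[[3]]; added <- added + 1L
      }
    }
    if (added < n) {
      warning("noise generation stalled: only ", added, " of ", n,
              " records placed without creating spurious compensated PCUs",
              call. = FALSE)
    }
  }
  if (cfg$n_tfs > 0 && cfg$n_regulators > 0) {
    add_noise(cfg$n_random_binding_edges, function() {
      tibble::tibble(tf = sample(tfs, 1), target = sample(regs, 1))
    }, "binding")
  }
  add_noise(cfg$n_random_physical, function() {
    pair <- sample(genes, 2)
    tibble::tibble(gene_a = pair[1], gene_b = pair[2],
                   throughput = if (stats::runif(1) < cfg$high_throughput_fraction)
                     "high" else "low")
  }, "physical")
  add_noise(cfg$n_random_genetic, function() {
    pair <- sample(genes, 2)
    tibble::tibble(gene_a = pair[1], gene_b = pair[2],
                   category = sample(categories, 1))
  }, "genetic")

  list(dataset = interaction_dataset(binding, physical, genetic),
       truth = truth)
}

#' Hand-built GAL-network fixture
#'
#' A small interaction dataset encoding the yeast galactose network
#' wiring: Gal4 binds the promoters of GAL3, GAL80 and GAL1; Gal80
#' physically interacts with Gal4 (direct inhibitor); Gal3 physically
#' interacts with Gal80 (indirect activator, sequestering Gal80); and
#' the regulators carry a positive-class genetic interaction (different
#' regulatory signs) plus a GAL80-GAL4 genetic record. The motif scan
#' finds exactly one compensated PCU: (GAL4; GAL3, GAL80).
#'
#' @return An [interaction_dataset()].
#' @examples
#' classify_pcus(gal_fixture())
#' @export
gal_fixture <- function() {
  interaction_dataset(
    tf_binding = tibble::tibble(
      tf = "GAL4", target = c("GAL3", "GAL80", "GAL1")
    ),
    physical = tibble::tibble(
      gene_a = c("GAL80", "GAL3"), gene_b = c("GAL4", "GAL80"),
      throughput = "low"
    ),
    genetic = tibble::tibble(
      gene_a = c("GAL3", "GAL80"), gene_b = c("GAL80", "GAL4"),
      category = c("synthetic rescue", "negative genetic")
    )
  )
}
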