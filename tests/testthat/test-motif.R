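test_that("physical-pair support applies the evidence threshold", {
  ds <- interaction_dataset(
    physical = tibble::tibble(
      gene_a = c("A", "B", "B", "C", "E"),
      gene_b = c("B", "C", "C", "B", "F"),
      throughput = c("low", "high", "high", "high", "high")
    )
  )
  expect_true(physical_pair_supported(ds, "A", "B"))   # one low-throughput
  expect_true(physical_pair_supported(ds, "B", "A"))   # unordered
  expect_true(physical_pair_supported(ds, "B", "C"))   # three high-throughput
  expect_false(physical_pair_supported(ds, "E", "F"))  # single high-throughput
  expect_false(physical_pair_supported(ds, "A", "C"))  # no records
  expect_true(physical_pair_supported(ds, "a", "b"))   # case-normalized
})

test_that("genetic categories classify into sign-evidence classes", {
  expect_equal(
    classify_genetic_category(c("synthetic rescue", "positive genetic",
                                "dosage growth defect", "dosage lethality")),
    rep("positive", 4))
  expect_equal(
    classify_genetic_category(c("dosage rescue", "negative genetic",
                                "synthetic growth defect",
                                "synthetic lethality",
                                "synthetic haploinsufficiency")),
    rep("negative", 5))
  expect_equal(
    classify_genetic_category(c("phenotypic enhancement",
                                "phenotypic suppression")),
    rep("ambiguous", 2))
  expect_equal(classify_genetic_category("Synthetic Rescue"), "positive")
  expect_equal(classify_genetic_category("made-up label"), "unrecognized")
})

test_that("sign relation aggregates evidence with override precedence", {
  ds <- interaction_dataset(
    genetic = tibble::tibble(
      gene_a = c("A", "A", "C", "C", "E", "G"),
      gene_b = c("B", "B", "D", "D", "F", "H"),
      category = c("synthetic rescue", "dosage lethality",  # pos, pos
                   "negative genetic", "positive genetic",  # mixed
                   "phenotypic enhancement",                # ambiguous only
                   "synthetic lethality")                   # neg
    ),
    overrides = tibble::tibble(gene_a = "E", gene_b = "F",
                               relation = "different")
  )
  expect_equal(sign_relation(ds, "A", "B"), "different")
  expect_equal(sign_relation(ds, "C", "D"), "conflict")
  expect_equal(sign_relation(ds, "G", "H"), "same")
  expect_equal(sign_relation(ds, "E", "F"), "different") # override wins
  expect_equal(sign_relation(ds, "X", "Y"), "unknown")
})

test_that("the GAL fixture yields exactly one compensated PCU", {
  scan <- motif_scan(gal_fixture())
  expect_equal(nrow(scan$pcus), 1)
  expect_equal(scan$pcus$tf, "GAL4")
  expect_equal(scan$pcus$regulator1, "GAL3")
  expect_equal(scan$pcus$regulator2, "GAL80")
  expect_equal(scan$pcus$sign_relation, "different")
  expect_equal(scan$pcus$direct_regulator, "second") # Gal80 touches Gal4
  expect_equal(scan$pcus$classification, "compensated")
  expect_equal(nrow(scan$networks), 1)
  expect_equal(scan$networks$n_compensated, 1L)
})

test_that("each PCU condition is load-bearing on the GAL fixture", {
  base <- gal_fixture()
  # condition 2 (regulator connectivity): drop the GAL3-GAL80 physical edge
  ds <- base
  ds$physical <- ds$physical[!(ds$physical$gene_a == "GAL3"), ]
  expect_equal(nrow(enumerate_pcus(ds)), 0)
  # condition 1 (TF contact): drop the GAL80-GAL4 physical edge
  ds <- base
  ds$physical <- ds$physical[!(ds$physical$gene_b == "GAL4"), ]
  expect_equal(nrow(enumerate_pcus(ds)), 0)
  # condition 3: drop the regulator-regulator genetic record
  ds <- base
  ds$genetic <- ds$genetic[ds$genetic$gene_a != "GAL3", ]
  expect_equal(nrow(enumerate_pcus(ds)), 0)
  # condition 4: drop the TF-regulator genetic record
  ds <- base
  ds$genetic <- ds$genetic[ds$genetic$gene_b != "GAL4", ]
  expect_equal(nrow(enumerate_pcus(ds)), 0)
  # promoter binding is required for both regulators
  ds <- base
  ds$tf_binding <- ds$tf_binding[ds$tf_binding$target != "GAL3", ]
  expect_equal(nrow(enumerate_pcus(ds)), 0)
})

test_that("sign flips and dual direct contact change the classification", {
  ds <- gal_fixture()
  ds$genetic$category[ds$genetic$gene_a == "GAL3"] <- "synthetic lethality"
  pcus <- classify_pcus(ds)
  expect_equal(pcus$classification, "non_compensated")
  # both regulators in direct contact with the TF
  ds2 <- gal_fixture()
  ds2$physical <- dplyr::bind_rows(
    ds2$physical,
    tibble::tibble(gene_a = "GAL3", gene_b = "GAL4", throughput = "low"))
  pcus2 <- classify_pcus(ds2)
  expect_equal(pcus2$direct_regulator, "both")
  expect_equal(pcus2$classification, "non_compensated")
  # unknown sign leaves the PCU indeterminate
  ds3 <- gal_fixture()
  ds3$genetic$category[ds3$genetic$gene_a == "GAL3"] <-
    "phenotypic enhancement"
  expect_equal(classify_pcus(ds3)$classification, "indeterminate")
})

test_that("global regulators are excluded from PCUs", {
  ds <- gal_fixture()
  ds$global_regulators <- "GAL80"
  expect_equal(nrow(enumerate_pcus(ds)), 0)
  ds$global_regulators <- "GAL4"
  expect_equal(nrow(enumerate_pcus(ds)), 0)
})

test_that("enumeration is invariant to record order", {
  cfg <- synth_config(n_tfs = 4, n_regulators = 12,
                      n_planted_compensated = 2,
                      n_planted_noncompensated = 2,
                      n_random_binding_edges = 10, n_random_physical = 10,
                      n_random_genetic = 10, seed = 77L)
  gen <- generate_interaction_dataset(cfg)
  ds <- gen$dataset
  shuffled <- withr::with_seed(3, interaction_dataset(
    tf_binding = ds$tf_binding[sample(nrow(ds$tf_binding)), ],
    physical = ds$physical[sample(nrow(ds$physical)), ],
    genetic = ds$genetic[sample(nrow(ds$genetic)), ]
  ))
  expect_equal(classify_pcus(ds), classify_pcus(shuffled))
})

test_that("merging links PCUs sharing genes into one network", {
  pcus <- tibble::tibble(
    tf = c("T1", "T2", "T3"),
    regulator1 = c("A", "A", "X"),
    regulator2 = c("B", "C", "Y"),
    direct_regulator = "first",
    sign_relation = "different",
    classification = c("compensated", "non_compensated", "compensated")
  )
  nets <- merge_pcus(pcus)
  expect_equal(nrow(nets), 2) # T1/T2 share regulator A
  big <- nets[nets$n_pcus == 2, ]
  expect_setequal(big$genes[[1]], c("T1", "T2", "A", "B", "C"))
  expect_equal(big$n_compensated, 1L)
  expect_equal(merge_pcus(pcus[0, ]) |> nrow(), 0)
})
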