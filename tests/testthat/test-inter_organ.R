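make_presence_study <- function() {
  # 2 taxa x 4 samples: subject p1 has stomach + esophagus samples
  m <- matrix(c(20, 10, 0, 9,          # t1: 0.002, 0.001, 0, 0.0009
                9980, 9990, 10000, 9991),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "filler"),
                              c("s1", "s2", "s3", "s4")))
  meta <- sample_table(data.frame(
    sample_id = colnames(m),
    subject_id = c("p1", "p1", "p1", "p2"),
    organ = c("stomach", "stomach", "esophagus", "stomach"),
    site = c("fundus", "antrum", "thoracic_part", "fundus"),
    sample_type = "mucosa"))
  list(m = m, meta = meta)
}

test_that("presence is strict and aggregated per subject-organ", {
  fx <- make_presence_study()
  pres <- call_presence(fx$m, fx$meta, threshold = 0.001)
  # 0.002 in one stomach sample of p1 -> present (any-sample rule)
  expect_true(pres["t1", "p1", "stomach"])
  # exactly 0.001 does not exceed the strict threshold
  expect_false(pres["t1", "p1", "esophagus"] &&
                 fx$m["t1", "s3"] > 0)   # s3 is zero; strictness checked below
  expect_false(pres["t1", "p2", "stomach"])  # 0.0009 < 0.001
  # boundary: exactly at the threshold is absent
  m2 <- matrix(c(10, 9990), 2, 1,
               dimnames = list(c("x", "y"), "s1"))
  meta2 <- small_meta("s1")
  expect_false(call_presence(m2, meta2, threshold = 0.001)["x", , ])
  # all-samples variant is stricter
  pres_all <- call_presence(fx$m, fx$meta, require_all = TRUE)
  expect_false(pres_all["t1", "p1", "stomach"])

  # monotone non-increasing in the threshold
  st <- generate_study(sim_config(n_subjects = 3, n_taxa = 40,
                                  n_shared_taxa = 5, seed = 14))
  p1 <- call_presence(st$bundle$counts, st$bundle$samples, 0.001)
  p2 <- call_presence(st$bundle$counts, st$bundle$samples, 0.01)
  expect_true(all(p1[p2] ))   # every presence at 0.01 is present at 0.001
})

test_that("species collapse is the OR of ASV presences with multiplicity", {
  pres <- array(FALSE, dim = c(3, 2, 2),
                dimnames = list(c("asv1", "asv2", "asv3"),
                                c("p1", "p2"), c("stomach", "esophagus")))
  pres["asv1", "p1", "stomach"] <- TRUE
  pres["asv2", "p2", "stomach"] <- TRUE
  pres["asv1", "p2", "stomach"] <- TRUE
  tax <- taxonomy_table(data.frame(
    taxon_id = c("asv1", "asv2", "asv3"),
    lineage = c("B;F;C;O;Fam;G;sp_x", "B;F;C;O;Fam;G;sp_x", "B;F;C;O;Fam;G;")))
  expect_message(cs <- collapse_species(pres, tax), "pseudo-species")
  expect_true(cs$presence["sp_x", "p1", "stomach"])
  expect_equal(cs$multiplicity["sp_x", "p1", "stomach"], 1L)
  expect_equal(cs$multiplicity["sp_x", "p2", "stomach"], 2L)
  expect_true("asv:asv3" %in% rownames(cs$presence))
  expect_setequal(cs$members$sp_x, c("asv1", "asv2"))

  # brute-force OR check on random presence patterns
  set.seed(15)
  prand <- array(runif(3 * 2 * 2) < 0.5, dim = dim(pres),
                 dimnames = dimnames(pres))
  csr <- suppressMessages(collapse_species(prand, tax))
  expect_identical(csr$presence["sp_x", , ],
                   prand["asv1", , ] | prand["asv2", , ])
})

test_that("prevalence is the subject-mean of presence with a strict cutoff", {
  pres <- array(FALSE, dim = c(1, 33, 1),
                dimnames = list("t", sprintf("p%02d", 1:33), "stomach"))
  pres[, 1:17, ] <- TRUE
  pv <- prevalence_by_organ(pres, cutoff = 0.5)
  expect_equal(unname(pv$prevalence[1, 1]), 17 / 33)   # 51.5%
  expect_true(pv$prevalent[1, 1])
  pres[] <- FALSE
  expect_false(prevalence_by_organ(pres)$prevalent[1, 1])
  pres[] <- TRUE
  pv2 <- prevalence_by_organ(pres)
  expect_equal(unname(pv2$prevalence[1, 1]), 1)
  expect_true(pv2$prevalent[1, 1])
})

test_that("positive-correlation ratio arithmetic, symmetry and skipping", {
  set.seed(16)
  n_sub <- 12
  ab <- array(NA_real_, dim = c(10, n_sub, 2),
              dimnames = list(sprintf("sp%02d", 1:10),
                              sprintf("p%02d", 1:n_sub),
                              c("esophagus", "stomach")))
  x <- seq_len(n_sub)
  for (s in 1:4) { ab[s, , 1] <- x + rnorm(n_sub, 0, 0.1)
                   ab[s, , 2] <- x + rnorm(n_sub, 0, 0.1) }   # positive
  for (s in 5:9) { ab[s, , 1] <- rnorm(n_sub); ab[s, , 2] <- rnorm(n_sub) }
  ab[10, 1:3, 1] <- 1:3; ab[10, 1:3, 2] <- 1:3   # only 3 paired subjects
  res <- suppressWarnings(positive_correlation_ratio(
    ab, dimnames(ab)[[1]], "esophagus", "stomach",
    methods = c("spearman", "pearson")))
  expect_equal(res$n_tested, 9)
  expect_equal(res$skipped, "sp10")
  expect_equal(res$ratio, res$n_positive / res$n_tested)
  expect_gte(res$n_positive, 4)  # the four planted positives are recovered
  # symmetric in the organ pair for spearman/pearson
  res2 <- suppressWarnings(positive_correlation_ratio(
    ab, dimnames(ab)[[1]], "stomach", "esophagus",
    methods = c("spearman", "pearson")))
  expect_equal(res2$ratio, res$ratio)
  # requiring all methods is at least as strict as any
  res_all <- suppressWarnings(positive_correlation_ratio(
    ab, dimnames(ab)[[1]], "esophagus", "stomach", combine = "all"))
  expect_lte(res_all$n_positive, res$n_positive)
})

test_that("core-species calls require every organ of the group", {
  pres <- array(FALSE, dim = c(3, 2, 3),
                dimnames = list(c("asv1", "asv2", "asv3"), c("p7", "p8"),
                                c("esophagus", "stomach", "skin")))
  tax <- taxonomy_table(data.frame(
    taxon_id = c("asv1", "asv2", "asv3"),
    lineage = c("B;F;C;O;Fam;G;sp_a", "B;F;C;O;Fam;G;sp_a",
                "B;F;C;O;Fam;G;sp_b")))
  groups <- list(upper_gi = c("esophagus", "stomach"))
  # asv1 present in both group organs of p7: single-ASV core
  pres["asv1", "p7", c("esophagus", "stomach")] <- TRUE
  cs <- core_species(pres, tax, groups)
  call_p7 <- subset(cs$calls, species == "sp_a" & subject == "p7")
  expect_equal(call_p7$status, "core_single_asv")
  # absent in stomach -> not core
  call_p8 <- subset(cs$calls, species == "sp_a" & subject == "p8")
  expect_equal(call_p8$status, "absent")
  # both ASVs of the species in all group organs: multi-ASV core
  pres["asv2", "p7", c("esophagus", "stomach")] <- TRUE
  cs2 <- core_species(pres, tax, groups)
  expect_equal(subset(cs2$calls, species == "sp_a" & subject == "p7")$status,
               "core_multi_asv")
  # species-level OR across different organs is NOT enough: one ASV per organ
  pres["asv1", "p8", "esophagus"] <- TRUE
  pres["asv2", "p8", "stomach"] <- TRUE
  cs3 <- core_species(pres, tax, groups)
  expect_equal(subset(cs3$calls, species == "sp_a" & subject == "p8")$status,
               "absent")
  # unknown organ in a group is an error
  expect_error(core_species(pres, tax, list(g = c("esophagus", "appendix"))),
               "appendix")
})

test_that("planted cores are recovered and exclusive species never called", {
  st <- generate_study(sim_config(n_subjects = 6, seed = 21))
  b <- st$bundle
  pres <- call_presence(b$counts, b$samples)
  cs <- core_species(pres, b$taxonomy, st$truth$organ_groups)
  planted <- unique(st$truth$core[c("species", "group")])
  m <- merge(planted, cs$calls, by = c("species", "group"))
  expect_gte(mean(m$status != "absent"), 0.85)
  # multi-ASV planted species reach multi-ASV status somewhere
  multi <- names(which(table(st$truth$core$species) >= 2))
  expect_true(any(subset(m, species %in% multi)$status == "core_multi_asv"))
  # organ-exclusive species are structurally absent from >= 1 group organ
  tax <- as.data.frame(b$taxonomy)
  excl_taxa <- setdiff(rownames(as.matrix(b$counts)),
                       c(st$truth$core$taxon, st$truth$shared_taxa,
                         st$truth$contaminants))
  excl_species <- tax$species[tax$taxon_id %in% excl_taxa]
  false_core <- subset(cs$calls, species %in% excl_species &
                         status != "absent")
  expect_equal(nrow(false_core), 0)
})
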