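test_that("basis solver matches a direct solve when nothing is excluded", {
  set.seed(31)
  D <- 8; n <- 100
  frac <- apply(matrix(rlnorm(D * n, 0, 1), D, n), 2, function(x) x / sum(x))
  rownames(frac) <- sprintf("T%02d", 1:D)
  # exclusion disabled: threshold above any attainable |rho|
  R <- sparcc_fractions(frac, n_exclusion_iterations = 0,
                        exclusion_threshold = 1.5)
  # independent direct solve of the full basis-variance system
  lf <- log(frac)
  S <- cov(t(lf)); v <- diag(S)
  Tm <- outer(v, v, "+") - 2 * S
  A <- matrix(1, D, D); diag(A) <- D - 1
  w <- solve(A, rowSums(Tm) - diag(Tm))
  R_direct <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w)))
  R_direct <- pmin(pmax(R_direct, -1), 1); diag(R_direct) <- 1
  expect_equal(unname(R), unname(R_direct), tolerance = 1e-8)
})

test_that("SparCC output is symmetric, unit-diagonal, deterministic and
           sample-order invariant", {
  m <- rand_counts(8, 30, seed = 32, lambda = 200)
  res1 <- sparcc(m, n_permutations = 0, seed = 5)
  res2 <- sparcc(m, n_permutations = 0, seed = 5)
  expect_identical(res1$correlation, res2$correlation)
  R <- res1$correlation
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 8))
  expect_true(all(abs(R) <= 1))
  # the deterministic core is exactly invariant to sample relabeling
  frac <- apply(m + 1, 2, function(x) x / sum(x))
  rownames(frac) <- rownames(m)
  ord <- sample(ncol(m))
  expect_equal(sparcc_fractions(frac), sparcc_fractions(frac[, ord]))

  expect_error(sparcc(rand_counts(3, 30, seed = 1)), "at least 4 taxa")
  expect_warning(sparcc(rand_counts(6, 8, seed = 1), n_permutations = 0),
                 "fewer than 10")
})

test_that("a planted proportional pair is detected against a null backdrop", {
  set.seed(33)
  D <- 14; n <- 150
  base <- matrix(rlnorm(D * n, 0, 1), D, n)
  base[2, ] <- base[1, ] * 2            # perfectly proportional pair
  frac <- apply(base, 2, function(x) x / sum(x))
  rownames(frac) <- sprintf("T%02d", 1:D)
  counts <- counts_from_fractions(frac, depth = 20000, seed = 33)
  res <- sparcc(counts, n_permutations = 60, seed = 7)
  expect_gt(res$correlation["T01", "T02"], 0.9)
  expect_lt(res$pseudo_p["T01", "T02"], 0.05)
  others <- abs(res$correlation[upper.tri(res$correlation)])
  expect_lt(median(others[-1]), 0.15)
})

test_that("cross-site consistency retains only same-sign, significant edges", {
  taxa <- c("A", "B", "C", "D")
  mk <- function(rAB, pAB, base_p = 0.9) {
    R <- diag(4); dimnames(R) <- list(taxa, taxa)
    P <- matrix(base_p, 4, 4, dimnames = list(taxa, taxa)); diag(P) <- NA
    R["A", "B"] <- R["B", "A"] <- rAB
    P["A", "B"] <- P["B", "A"] <- pAB
    list(correlation = R, pseudo_p = P)
  }
  # significant, same sign at all three sites: kept with the mean correlation
  nw <- consistent_organ_correlations(
    list(s1 = mk(0.4, 0.001), s2 = mk(0.5, 0.001), s3 = mk(0.6, 0.001)),
    fdr_alpha = 0.05, organ = "stomach")
  expect_equal(nrow(nw), 1)
  expect_equal(nw$taxon_a, "A"); expect_equal(nw$taxon_b, "B")
  expect_equal(nw$mean_correlation, 0.5)

  # sign flip at one site: dropped
  nw2 <- consistent_organ_correlations(
    list(s1 = mk(0.4, 0.001), s2 = mk(-0.5, 0.001)), fdr_alpha = 0.05)
  expect_equal(nrow(nw2), 0)

  # not significant at one site: dropped
  nw3 <- consistent_organ_correlations(
    list(s1 = mk(0.4, 0.001), s2 = mk(0.5, 0.2)), fdr_alpha = 0.05)
  expect_equal(nrow(nw3), 0)

  # monotone in alpha: tightening never adds edges
  per_site <- list(s1 = mk(0.4, 0.02), s2 = mk(0.5, 0.03))
  for (pair in list(c(0.5, 0.05), c(0.05, 0.01))) {
    loose <- consistent_organ_correlations(per_site, fdr_alpha = pair[1])
    tight <- consistent_organ_correlations(per_site, fdr_alpha = pair[2])
    expect_true(all(paste(tight$taxon_a, tight$taxon_b) %in%
                      paste(loose$taxon_a, loose$taxon_b)))
  }
})

test_that("organ-specific edge rules follow the two criteria", {
  mk_nw <- function(edges, organ) {
    df <- data.frame(taxon_a = edges$a, taxon_b = edges$b,
                     mean_correlation = edges$r, max_q = 0.01,
                     stringsAsFactors = FALSE)
    attr(df, "organ") <- organ
    class(df) <- c("organ_network", "data.frame")
    df
  }
  # edge at 0.7 only in the large intestine: unique-strength specific
  nets <- list(
    large_intestine = mk_nw(list(a = c("A", "C"), b = c("B", "D"),
                                 r = c(0.7, 0.5)), "large_intestine"),
    stomach = mk_nw(list(a = "C", b = "D", r = -0.2), "stomach"),
    esophagus = mk_nw(list(a = "C", b = "D", r = 0.5), "esophagus"))
  ann <- organ_specific_edges(nets)
  li <- ann$large_intestine
  expect_true(li$specific[li$taxon_a == "A"])
  expect_match(li$specificity_reason[li$taxon_a == "A"], "unique_strength")
  # C-D: 0.5 in LI vs -0.2 in stomach (diff 0.7 > 0.6) but 0.5 in esophagus
  # (diff 0) -> not specific under the every-other-organ rule...
  expect_false(li$specific[li$taxon_a == "C"])
  # ...but specific under the any-organ variant
  ann2 <- organ_specific_edges(nets, any_organ = TRUE)
  expect_true(ann2$large_intestine$specific[2])

  # two organs only: 0.5 vs -0.2 is difference-specific both ways
  nets2 <- nets[c("large_intestine", "stomach")]
  nets2$large_intestine <- nets2$large_intestine[2, ]
  ann3 <- organ_specific_edges(nets2)
  expect_true(ann3$large_intestine$specific)
  expect_match(ann3$large_intestine$specificity_reason, "difference")
  # identical correlation everywhere: not specific
  nets3 <- list(a = mk_nw(list(a = "X", b = "Y", r = 0.5), "a"),
                b = mk_nw(list(a = "X", b = "Y", r = 0.5), "b"))
  ann4 <- organ_specific_edges(nets3)
  expect_false(ann4$a$specific)
})

test_that("the per-organ pipeline finds planted organ-specific pairs", {
  # the planted pair sits on low-mass shared taxa: closure to the simplex
  # barely attenuates the planted correlation, and the pair is comparable
  # across organs (it is only coupled in the large intestine)
  cfg <- sim_config(
    n_subjects = 40,
    organs = list(
      stomach = list(sites = "fundus", types = "mucosa"),
      large_intestine = list(sites = "sigmoid_colon", types = "mucosa")),
    n_taxa = 20, n_controls = 0, n_shared_taxa = 8,
    organ_groups = list(),
    core_species = data.frame(species = character(), group = character(),
                              n_asv = integer()),
    n_enriched_per_organ = 0,
    network_effects = data.frame(
      organ = "large_intestine", taxon_a = "ASV_0001", taxon_b = "ASV_0002",
      latent_r = 0.9, stringsAsFactors = FALSE),
    contaminants = list(n = 0, control_prevalence = 0, carryover = 0,
                        mean_proportion = 0),
    # beta-binomial overdispersion scales as rho/p for rare taxa, so a
    # correlation benchmark needs a modest rho to stay detectable
    sample_log_sigma = 0.4, rho = 0.005, shared_weight = 0.02, seed = 99)
  st <- generate_study(cfg)
  # many permutations (one resample each) so BH over all edges can resolve
  nets <- suppressWarnings(organ_networks(
    st$bundle$counts, st$bundle$samples, taxa_min_prevalence = 0.5,
    min_site_samples = 5, n_permutations = 4000, n_perm_resamples = 1,
    seed = 17))
  li <- nets$large_intestine
  planted <- li[li$taxon_a == "ASV_0001" & li$taxon_b == "ASV_0002", ]
  expect_equal(nrow(planted), 1)
  expect_gt(planted$mean_correlation, 0.5)
  # coupled nowhere else: the edge is annotated organ-specific
  expect_true(planted$specific)
})
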