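# Co-expression network construction: correlations, soft-threshold scan,
# TOM, module detection, eigenmetabolites, module-trait statistics and hub
# selection.

test_that("metabolite correlations behave on duplicates, nulls and planted blocks", {
  sim <- three_block_metabolome(seed = 1)
  m <- sim$abundance
  # duplicated metabolite rows correlate perfectly
  dup <- rbind(m[1:5, ], m[1, , drop = FALSE])
  rownames(dup)[6] <- "copy"
  r <- metabolite_correlation(dup)
  expect_equal(unname(r["copy", rownames(m)[1]]), 1)
  # independent metabolites: |r| stays small at n = 100
  set.seed(23)
  null_m <- matrix(exp(rnorm(60 * 100, 8, 0.5)), 60,
                   dimnames = list(paste0("m", 1:60), paste0("s", 1:100)))
  rn <- metabolite_correlation(null_m)
  expect_lt(quantile(abs(rn[upper.tri(rn)]), 0.95), 0.25)
  # planted blocks sit near the target correlation
  rb <- metabolite_correlation(m)
  block1 <- names(sim$truth$module_map)[sim$truth$module_map == 1]
  rb1 <- rb[block1, block1]
  expect_gt(mean(rb1[upper.tri(rb1)]), 0.6)
  expect_lt(mean(rb1[upper.tri(rb1)]), 0.9)
  # zero-variance metabolites are dropped with a warning
  flat <- m
  flat[3, ] <- 5
  expect_warning(rf <- metabolite_correlation(flat), rownames(m)[3])
  expect_equal(nrow(rf), nrow(m) - 1)
})

test_that("adjacency and TOM follow their closed forms", {
  r <- matrix(c(1, 0.5, -0.3,
                0.5, 1, 0.8,
                -0.3, 0.8, 1), 3)
  a1 <- adjacency_matrix(r, 1)
  expect_equal(a1[1, 2], 0.5)
  expect_equal(a1[1, 3], 0.3)       # unsigned
  expect_equal(diag(a1), rep(0, 3))
  expect_equal(adjacency_matrix(r, 4)[1, 2], 0.0625)
  # all-0.5 triangle: TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  A <- matrix(0.5, 3, 3); diag(A) <- 0
  tom <- tom_matrix(A)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(diag(tom), rep(1, 3))
  # empty adjacency has no overlap
  A0 <- matrix(0, 4, 4)
  expect_equal(tom_matrix(A0)[1, 2], 0)
  # star graph: center-leaf pairs have no shared neighbours, TOM = A there
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.6
  tstar <- tom_matrix(star)
  expect_equal(tstar[1, 2:5], star[1, 2:5])
  # bounds and symmetry on random valid adjacencies
  set.seed(23)
  for (i in 1:5) {
    rr <- cor(matrix(rnorm(20 * 30), 30))
    aa <- adjacency_matrix(rr, sample(2:6, 1))
    tt <- tom_matrix(aa)
    expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
    expect_equal(tt, t(tt), tolerance = 1e-12)
  }
})

test_that("soft-threshold scan finds scale-free powers and degrades gracefully", {
  # heavy-tailed factor loadings emulate a hub-dominated network
  set.seed(29)
  n <- 150; p <- 100
  loads <- sort(runif(p)^3, decreasing = TRUE)
  h <- rnorm(n)
  x <- sapply(loads, function(w) sqrt(w) * h + sqrt(1 - w) * rnorm(n))
  r <- cor(x)
  scan <- soft_threshold_scan(r, rsq_target = 0.85)
  expect_false(is.na(scan$chosen_power))
  chosen <- scan$fit[scan$fit$power == scan$chosen_power, ]
  expect_gte(chosen$signed_rsq, 0.85)
  # mean connectivity decreases in the power
  expect_true(all(diff(scan$fit$mean_connectivity) < 0))
  # constant off-diagonal correlation: fit undefined at every power
  rc <- matrix(0.5, 30, 30); diag(rc) <- 1
  scanc <- soft_threshold_scan(rc)
  expect_true(all(is.na(scanc$fit$signed_rsq)))
  expect_true(is.na(scanc$chosen_power))
})

test_that("module detection recovers planted blocks and rejects noise", {
  sim <- three_block_metabolome(seed = 1)
  r <- metabolite_correlation(sim$abundance)
  tom <- tom_matrix(adjacency_matrix(r, 4))
  part <- detect_modules(1 - tom, min_module_size = 5)
  expect_equal(length(part$sizes), 3)
  expect_equal(adjusted_rand_index(part$module,
                                   sim$truth$module_map[names(part$module)]),
               1)
  # invariant to metabolite input order (up to label permutation)
  set.seed(2)
  perm <- sample(nrow(sim$abundance))
  r2 <- metabolite_correlation(sim$abundance[perm, ])
  tom2 <- tom_matrix(adjacency_matrix(r2, 4))
  part2 <- detect_modules(1 - tom2, min_module_size = 5)
  common <- names(part$module)
  expect_equal(adjusted_rand_index(part$module[common],
                                   part2$module[common]), 1)
  # fully independent metabolites: mostly unassigned
  set.seed(31)
  null_m <- matrix(exp(rnorm(60 * 100, 8, 0.5)), 60,
                   dimnames = list(paste0("m", 1:60), paste0("s", 1:100)))
  rn <- metabolite_correlation(null_m)
  tn <- tom_matrix(adjacency_matrix(rn, 4))
  pn <- detect_modules(1 - tn, min_module_size = 10)
  expect_gte(pn$n_unassigned / 60, 0.8)
  # a single all-encompassing block is one module
  one <- simulate_metabolome_cohort(metabolome_sim_config(
    n_gc = 80, n_healthy = 0, n_metabolites = 30,
    module_spec = list(list(size = 30, within_correlation = 0.8,
                            trait_correlation = 0)),
    dem_spec = list(), seed = 3))
  ro <- metabolite_correlation(one$abundance)
  po <- detect_modules(1 - tom_matrix(adjacency_matrix(ro, 4)),
                       min_module_size = 5)
  expect_equal(length(po$sizes), 1)
  expect_equal(sum(po$module == 1), 30)
  expect_error(detect_modules(1 - tom, min_module_size = 1), ">= 2")
})

test_that("eigenmetabolites summarise modules and orient deterministically", {
  sim <- three_block_metabolome(seed = 1)
  z <- standardize_metabolome(sim$abundance)
  part <- detect_modules(
    1 - tom_matrix(adjacency_matrix(cor(t(z)), 4)), min_module_size = 5)
  eig <- module_eigenmetabolites(z, part)
  expect_equal(dim(eig), c(ncol(z), 3))
  expect_equal(unname(apply(eig, 2, sd)), rep(1, 3))
  # members correlate strongly with their own eigenmetabolite
  for (m in 1:3) {
    members <- names(part$module)[part$module == m]
    mm <- abs(cor(t(z[members, ]), eig[, paste0("ME", m)]))
    expect_gte(mean(mm), 0.8)
    # oriented towards the module mean profile
    expect_gt(cor(eig[, paste0("ME", m)], colMeans(z[members, ])), 0)
  }
  # a module of identical metabolites IS its common profile
  ident <- matrix(rep(exp(rnorm(20, 8, 0.4)), each = 4), 4, byrow = FALSE,
                  dimnames = list(paste0("m", 1:4), paste0("s", 1:20)))
  zi <- standardize_metabolome(ident)
  ei <- module_eigenmetabolites(zi, setNames(rep(1L, 4), rownames(zi)))
  expect_equal(abs(cor(ei[, 1], zi[1, ])), 1)
  # flipping every member's sign leaves the membership strengths intact
  zneg <- -z
  eneg <- module_eigenmetabolites(zneg, part)
  for (m in 1:3) {
    members <- names(part$module)[part$module == m]
    expect_equal(abs(cor(t(zneg[members, ]), eneg[, paste0("ME", m)])),
                 abs(cor(t(z[members, ]), eig[, paste0("ME", m)])),
                 tolerance = 1e-10)
  }
})

test_that("module-trait statistics and hub selection implement the MM/MES rules", {
  # planted trait-linked module at the 51-sample IHC design scale
  cfg <- metabolome_sim_config(
    n_gc = 51, n_healthy = 0, n_metabolites = 120,
    module_spec = list(list(size = 20, within_correlation = 0.72,
                            trait_correlation = 0.5),
                       list(size = 15, within_correlation = 0.7,
                            trait_correlation = 0)),
    dem_spec = list(), seed = 41)
  sim <- simulate_metabolome_cohort(cfg)
  trait <- setNames(rep(NA_real_, ncol(sim$abundance)),
                    colnames(sim$abundance))
  trait[names(sim$truth$her2)] <- sim$truth$her2
  fit <- wmcna(sim$abundance, trait)
  # the module carrying most planted trait-module members is significant
  planted <- names(sim$truth$module_map)[sim$truth$module_map == 1]
  mod_of_planted <- fit$partition$module[planted]
  main <- as.integer(names(which.max(table(mod_of_planted[mod_of_planted > 0]))))
  stats_row <- fit$stats$module_stats[fit$stats$module_stats$module == main, ]
  expect_lt(stats_row$p, 0.05)
  # hubs: mostly planted members, decent sensitivity
  expect_gte(mean(fit$hubs %in% planted), 0.9)
  expect_gte(length(fit$hubs), 5)
  # MES = 1 for a metabolite identical to the trait
  z <- fit$standardized
  z2 <- rbind(z, matrix(trait[colnames(z)], 1,
                        dimnames = list("trait_clone", colnames(z))))
  part2 <- fit$partition
  part2$module <- c(part2$module, trait_clone = 0L)
  st <- module_trait_stats(z2, part2, fit$eigens, trait)
  expect_equal(st$metabolite_stats$MES[st$metabolite_stats$id ==
                                         "trait_clone"], 1)
})

test_that("hub thresholds are strict and monotone", {
  stats <- structure(list(
    module_stats = data.frame(module = 1:2, size = c(3, 3),
                              r = c(0.6, 0.1), p = c(0.001, 0.7)),
    metabolite_stats = data.frame(
      id = c("exact", "in", "weak", "other_module", "strong_ns"),
      module = c(1, 1, 1, 2, 2),
      MM = c(0.70, 0.71, 0.9, 0.95, 0.99),
      MES = c(0.5, 0.16, 0.10, 0.5, 0.9)),
    method = "pearson", n_pairs = 51), class = "module_trait_stats")
  hubs <- select_hub_metabolites(stats)
  expect_equal(hubs, "in")        # MM = 0.70 exactly is excluded; module 2 not significant
  # raising a threshold never adds metabolites
  hubs2 <- select_hub_metabolites(stats, mm_min = 0.8)
  expect_true(all(hubs2 %in% hubs))
  # no significant modules: empty with warning
  stats$module_stats$p <- c(0.5, 0.7)
  expect_warning(none <- select_hub_metabolites(stats), "no trait")
  expect_length(none, 0)
})

test_that("module trait p-values are calibrated when the trait is independent", {
  # 100 replicates of a null trait against a planted (trait-free) module
  set.seed(37)
  pvals <- unlist(lapply(1:100, function(i) {
    sim <- simulate_metabolome_cohort(metabolome_sim_config(
      n_gc = 40, n_healthy = 0, n_metabolites = 25,
      module_spec = list(list(size = 12, within_correlation = 0.75,
                              trait_correlation = 0)),
      dem_spec = list(), seed = 500 + i))
    z <- standardize_metabolome(sim$abundance)
    part <- detect_modules(
      1 - tom_matrix(adjacency_matrix(cor(t(z)), 4)), min_module_size = 5)
    if (!length(part$sizes)) return(NULL)
    eig <- module_eigenmetabolites(z, part)
    trait <- setNames(sim$truth$her2[colnames(z)], colnames(z))
    module_trait_stats(z, part, eig, trait)$module_stats$p
  }))
  frac <- mean(pvals < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(pvals)) + 0.02)
})
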