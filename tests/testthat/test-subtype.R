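# Consensus subtyping: pathway subsetting, resampled consensus
# clustering, coexpressed-group selection, quadrant assignment, specific
# molecules, k-group tests and subtype survival.

test_that("pathway subsetting preserves order and reports missing genes", {
  m <- matrix(rnorm(20), 4, dimnames = list(c("a", "b", "c", "d"), NULL))
  sub <- subset_pathway_genes(m, c("d", "a"))
  expect_equal(rownames(sub), c("d", "a"))
  expect_length(attr(sub, "missing_genes"), 0)
  sub2 <- subset_pathway_genes(m, c("a", "x", "b", "y", "z"))
  expect_equal(rownames(sub2), c("a", "b"))
  expect_equal(attr(sub2, "missing_genes"), c("x", "y", "z"))
  expect_error(subset_pathway_genes(m, c("x", "y")), "no pathway genes")
})

test_that("consensus clustering separates planted gene blocks and is reproducible", {
  set.seed(7)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, k, rho = 0.9) t(sapply(seq_len(k), function(i)
    sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)))
  x <- rbind(block(f1, 10), block(f2, 10))
  rownames(x) <- paste0("g", 1:20)
  res <- consensus_cluster(x, consensus_params(k = 2, seed = 7))
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(res$labels, truth), 1)
  within <- res$consensus[1:10, 1:10]
  between <- res$consensus[1:10, 11:20]
  expect_gte(mean(within[upper.tri(within)]), 0.9)
  expect_lte(mean(between), 0.1)
  # bit-identical under the same seed
  res2 <- consensus_cluster(x, consensus_params(k = 2, seed = 7))
  expect_identical(res$consensus, res2$consensus)
  # consensus entries are proportions
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  # k equal to the item count: everything becomes a singleton
  xs <- x[1:6, ]
  deg <- consensus_cluster(xs, consensus_params(k = 6, p_item = 1,
                                                reps = 10, seed = 1))
  off <- deg$consensus[upper.tri(deg$consensus)]
  expect_true(all(off == 0))
  expect_equal(sort(unname(deg$labels)), 1:6)
  expect_error(consensus_cluster(xs, consensus_params(k = 10)), "exceeds")
})

test_that("the most coexpressed cluster is selected with documented tie-breaks", {
  set.seed(7)
  n <- 50
  f <- rnorm(n)
  core <- t(sapply(1:8, function(i) sqrt(0.8) * f + sqrt(0.2) * rnorm(n)))
  decoy <- matrix(rnorm(12 * n), 12)
  x <- rbind(core, decoy)
  rownames(x) <- paste0("g", 1:20)
  labels <- setNames(rep(c(1L, 2L), c(8, 12)), rownames(x))
  expect_equal(sort(select_coexpressed_group(x, labels)),
               sort(paste0("g", 1:8)))
  # anti-correlated cluster loses to a positively correlated one
  anti <- t(sapply(1:6, function(i)
    (if (i %% 2) 1 else -1) * f + 0.1 * rnorm(n)))
  weak <- t(sapply(1:6, function(i) sqrt(0.3) * f + sqrt(0.7) * rnorm(n)))
  x2 <- rbind(anti, weak)
  rownames(x2) <- paste0("h", 1:12)
  labels2 <- setNames(rep(c(1L, 2L), each = 6), rownames(x2))
  expect_equal(sort(select_coexpressed_group(x2, labels2)),
               sort(paste0("h", 7:12)))
  # exact tie (all mean pairwise r = 1): the larger cluster wins
  prof <- rnorm(n)
  tied <- matrix(rep(prof, 5), 5, byrow = TRUE,
                 dimnames = list(paste0("k", 1:5), NULL))
  labels3 <- setNames(c(1L, 1L, 2L, 2L, 2L), rownames(tied))
  expect_equal(sort(select_coexpressed_group(tied, labels3)),
               c("k3", "k4", "k5"))
  expect_error(select_coexpressed_group(x[1:2, ],
                                        setNames(1:2, rownames(x)[1:2])),
               "singleton")
})

test_that("pathway scores are medians of gene z-scores with their invariances", {
  set.seed(3)
  m <- matrix(rnorm(5 * 30, 10), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  sc <- pathway_score(m, rownames(m))
  # a sample sitting at every gene's mean scores 0
  m2 <- cbind(m, center = rowMeans(m))
  z <- (m2 - rowMeans(m2)) / apply(m2, 1, sd)
  expect_equal(unname(pathway_score(m2, rownames(m2))["center"]),
               unname(median(z[, "center"])))
  # shifting one gene by a constant changes nothing
  m3 <- m
  m3[2, ] <- m3[2, ] + 100
  expect_equal(pathway_score(m3, rownames(m3)), sc)
  # median arithmetic: sample s1 has gene z-values exactly (1, -1, 0.5)
  a <- (-0.5 + sqrt(3.25)) / 2
  b <- -0.5 - a
  mz <- rbind(c(1, -1, 0), c(-1, 1, 0), c(0.5, a, b)) * 3 + 10
  rownames(mz) <- paste0("g", 1:3); colnames(mz) <- paste0("s", 1:3)
  got <- pathway_score(mz, rownames(mz))
  expect_equal(unname(got["s1"]), 0.5)
  expect_error(pathway_score(m[, 1, drop = FALSE], rownames(m)), "2 samples")
})

test_that("quadrant assignment follows the boundary-inclusive rule exactly", {
  a <- c(s1 = 0, s2 = 0.3, s3 = 0, s4 = 0.3, s5 = -0.2)
  g <- c(s1 = 0, s2 = 0, s3 = 0.3, s4 = 0.3, s5 = -0.1)
  st <- assign_subtypes(a, g)
  expect_equal(as.character(st$subtype),
               c("quiescent", "AAG", "GG", "mixed", "quiescent"))
  # partition property: labels exhaust the scored samples
  set.seed(11)
  aa <- setNames(rnorm(200), paste0("x", 1:200))
  gg <- setNames(rnorm(200), paste0("x", 1:200))
  st2 <- assign_subtypes(aa, gg)
  expect_equal(nrow(st2), 200)
  expect_equal(sum(table(st2$subtype)), 200)
  # samples missing a score are excluded with a warning
  expect_warning(st3 <- assign_subtypes(aa[1:150], gg), "excluded")
  expect_equal(nrow(st3), 150)
})

test_that("the full pipeline recovers planted subtypes and cores", {
  cfg <- expression_sim_config(seed = 7)
  sim <- simulate_expression_cohort(cfg)
  sets <- make_gene_sets(cfg)
  ms <- metabolic_subtype(
    sim$expr, sets$KEGG_ALANINE_ASPARTATE_AND_GLUTAMATE_METABOLISM,
    sets$KEGG_GLYCOLYSIS_GLUCONEOGENESIS, consensus_params(seed = 7))
  expect_setequal(ms$aag$selected, sim$truth$aag_core)
  expect_setequal(ms$gg$selected, sim$truth$gg_core)
  lab <- setNames(as.character(ms$scores$subtype), ms$scores$sample_id)
  expect_gte(adjusted_rand_index(lab[names(sim$truth$subtype)],
                                 sim$truth$subtype), 0.9)
})

test_that("specific molecules require upregulation against every other subtype", {
  set.seed(47)
  n_per <- 100
  labels <- setNames(rep(c("quiescent", "AAG", "GG", "mixed"),
                         each = n_per), paste0("s", 1:(4 * n_per)))
  base <- matrix(rnorm(200 * 400), 200,
                 dimnames = list(paste0("f", 1:200), names(labels)))
  # marker up in AAG only; confounder up in AAG and GG
  marker <- rnorm(400) + 2 * (labels == "AAG")
  confound <- rnorm(400) + 2 * (labels %in% c("AAG", "GG"))
  x <- rbind(base, marker = marker, confound = confound)
  sp <- specific_molecules(x, labels)
  expect_true("marker" %in% sp$AAG)
  expect_false("confound" %in% unlist(sp))
  # null features: near-zero specific calls on average
  null_counts <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    xn <- matrix(rnorm(100 * 80), 100,
                 dimnames = list(paste0("f", 1:100), paste0("s", 1:80)))
    ln <- setNames(rep(c("quiescent", "AAG", "GG", "mixed"), each = 20),
                   colnames(xn))
    length(unlist(specific_molecules(xn, ln)))
  }, numeric(1))
  expect_lte(mean(null_counts), 0.01 * 100)
  # a subtype with < 2 samples is dropped with a warning
  small <- labels
  small[labels == "mixed"] <- "quiescent"
  small[1] <- "mixed"
  expect_warning(specific_molecules(x[1:20, ], small), "mixed")
})

test_that("k-group feature tests retain the ERBB2-like signal and stay calibrated", {
  cfg <- expression_sim_config(seed = 7)
  sim <- simulate_expression_cohort(cfg)
  labels <- sim$truth$subtype
  feats <- sim$expr[c("ERBB2", "GENE_00001", "GENE_00002"), ]
  res <- subtype_group_tests(feats, labels)
  erbb2 <- res[res$id == "ERBB2", ]
  expect_true(erbb2$retained)
  meds <- tapply(sim$expr["ERBB2", ], labels, median)
  expect_equal(names(which.min(meds)), "GG")
  # constant feature: tie-handled p = 1, not retained
  flat <- matrix(5, 1, ncol(sim$expr),
                 dimnames = list("flat", colnames(sim$expr)))
  rflat <- subtype_group_tests(flat, labels)
  expect_equal(rflat$p, 1)
  expect_false(rflat$retained)
  # null calibration: about 5% retained
  set.seed(49)
  xn <- matrix(rnorm(2000 * 120), 2000,
               dimnames = list(paste0("f", 1:2000), paste0("s", 1:120)))
  ln <- setNames(sample(c("quiescent", "AAG", "GG", "mixed"), 120,
                        replace = TRUE), colnames(xn))
  rn <- subtype_group_tests(xn, ln)
  expect_lt(abs(mean(rn$retained) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("subtype survival excludes exactly the unlabeled follow-up and tests k groups", {
  cfg <- expression_sim_config(seed = 7)
  sim <- simulate_expression_cohort(cfg)
  labels <- sim$truth$subtype
  sv <- subtype_survival(sim$clinical, labels, "OS")
  expect_equal(sv$test$df, 3)
  expect_lt(sv$test$p.value, 0.01)
  # GG sits lowest at median follow-up; mixed highest
  t_med <- median(sim$clinical$os_time)
  s_at <- vapply(sv$curves, km_survival_at, numeric(1), t = t_med)
  expect_equal(names(which.min(s_at)), "GG")
  expect_equal(names(which.max(s_at)), "mixed")
  # identical survival across subtypes: no signal
  cl <- sim$clinical
  base_t <- rep(sim$clinical$os_time[1:100], 4)
  base_e <- rep(sim$clinical$os_event[1:100], 4)
  cl2 <- data.frame(sample_id = cl$sample_id, os_time = base_t,
                    os_event = base_e)
  sv2 <- subtype_survival(cl2, setNames(rep(c("quiescent", "AAG", "GG",
                                              "mixed"), each = 100),
                                        cl$sample_id))
  expect_gt(sv2$test$p.value, 0.99)
  # missing follow-up rows are the only exclusions
  cl3 <- cl
  cl3$os_time[1:10] <- NA
  sv3 <- subtype_survival(cl3, labels)
  expect_equal(sv3$n_excluded, 10)
  expect_equal(sv3$n_used, nrow(cl) - 10)
  # one subtype fully censored still contributes a group (df stays 3)
  cl4 <- cl
  cl4$os_event[labels[cl4$sample_id] == "mixed"] <- 0
  sv4 <- subtype_survival(cl4, labels)
  expect_equal(sv4$test$df, 3)
  # DSS endpoint runs on the same table
  expect_equal(subtype_survival(cl, labels, "DSS")$endpoint, "DSS")
})
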