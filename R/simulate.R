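## Synthetic cohorts with planted ground truth: expression cohorts carrying
## two coexpressed pathway-gene cores that define four metabolic subtypes
## with subtype-dependent survival, and two-group serum metabolomes with
## planted fold changes and an HER2-linked correlated module. Every
## generator is deterministic under its config seed.

#' Configuration for the synthetic expression cohort
#'
#' The cohort emulates a tumour expression study in which two metabolic
#' pathways (alanine-aspartate-glutamate, "AAG", and
#' glycolysis/gluconeogenesis, "GG") each have a core of mutually
#' coexpressed genes whose activity is switched on in a subtype-dependent
#' way, defining four planted subtypes: quiescent (neither pathway on),
#' AAG, GG, and mixed (both on).
#'
#' Core genes are generated from a latent pathway-activity factor:
#' `activity = activity_shift * on + eta`, `eta ~ N(0, activity_noise_sd^2)`;
#' with `f` the standardized activity, gene g is
#' `mu_g + noise_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps)`, so the mean
#' pairwise core correlation equals `within_core_correlation` exactly in
#' expectation and core genes are shifted when the pathway is on.
#'
#' @param n_samples number of tumour samples (default 400).
#' @param n_background_genes unstructured genes (default 2000).
#' @param core_size,decoy_size per pathway: coexpressed core genes and
#'   non-coexpressed decoy members of the pathway gene set.
#' @param within_core_correlation target pairwise Pearson correlation of
#'   core genes, in \[0, 1).
#' @param subtype_proportions named proportions over
#'   quiescent/AAG/GG/mixed; must sum to 1.
#' @param activity_shift pathway-activity shift (in gene-SD units) when the
#'   pathway is on (default 1.5).
#' @param activity_noise_sd SD of the intrinsic pathway-activity noise
#'   relative to the shift (default 0.3).
#' @param noise_sd per-gene residual SD on the log2 scale (default 1).
#' @param baseline_hazard exponential event hazard per day for the
#'   reference subtypes (default 5e-4, median OS about 3.8 years).
#' @param log_hr named per-subtype log hazard ratios (default: GG at
#'   log 2 = worst, mixed at log 0.5 = best, others 0).
#' @param censoring_rate target fraction of censored subjects under
#'   uniform censoring (default 0.3).
#' @param seed RNG seed.
#' @return A validated list of class `subtype_sim_config`.
#' @export
expression_sim_config <- function(n_samples = 400,
                                  n_background_genes = 2000,
                                  core_size = 20,
                                  decoy_size = 20,
                                  within_core_correlation = 0.8,
                                  subtype_proportions = c(quiescent = 0.25,
                                                          AAG = 0.25,
                                                          GG = 0.25,
                                                          mixed = 0.25),
                                  activity_shift = 1.5,
                                  activity_noise_sd = 0.3,
                                  noise_sd = 1,
                                  baseline_hazard = 5e-4,
                                  log_hr = c(quiescent = 0, AAG = 0,
                                             GG = log(2), mixed = log(0.5)),
                                  censoring_rate = 0.3,
                                  seed = 1L) {
  cfg <- as.list(environment())
  subtypes <- c("quiescent", "AAG", "GG", "mixed")
  if (!setequal(names(subtype_proportions), subtypes))
    stop("subtype_proportions must be named quiescent/AAG/GG/mixed")
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stop("subtype_proportions must sum to 1")
  if (within_core_correlation < 0 || within_core_correlation >= 1)
    stop("infeasible within_core_correlation (must be in [0, 1))")
  if (activity_shift < 0) stop("activity_shift must be >= 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (!setequal(names(log_hr), subtypes))
    stop("log_hr must be named quiescent/AAG/GG/mixed")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  cfg$subtype_proportions <- subtype_proportions[subtypes]
  cfg$log_hr <- log_hr[subtypes]
  class(cfg) <- "subtype_sim_config"
  cfg
}

sim_gene_ids <- function(cfg) {
  pad <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))
  list(aag_core = pad("AAG_CORE", cfg$core_size),
       aag_decoy = pad("AAG_DECOY", cfg$decoy_size),
       gg_core = pad("GG_CORE", cfg$core_size),
       gg_decoy = pad("GG_DECOY", cfg$decoy_size),
       background = sprintf("GENE_%05d", seq_len(cfg$n_background_genes)))
}

## Uniform-censoring horizon giving the target expected censoring fraction
## under the exponential mixture of subtype hazards.
censoring_horizon <- function(rate, hazards, props) {
  if (rate <= 0) return(Inf)
  f <- function(tmax)
    sum(props * (1 - exp(-hazards * tmax)) / (hazards * tmax)) - rate
  uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

#' Simulate an expression cohort with planted metabolic subtypes
#'
#' @param cfg an [expression_sim_config()].
#' @return A list with `expr` (genes x samples log2 matrix), `clinical`
#'   (sample_id, group, OS/DSS time and event, stage, grade, her2_ihc,
#'   immune_subtype) and `truth` (per-sample `subtype`, per-pathway core
#'   and decoy gene ids, and the id of a planted `erbb2_like` gene whose
#'   expression is reduced in the GG subtype).
#' @export
simulate_expression_cohort <- function(cfg = expression_sim_config()) {
  stopifnot(inherits(cfg, "subtype_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  subtypes <- names(cfg$subtype_proportions)
  subtype <- sample(subtypes, n, replace = TRUE,
                    prob = cfg$subtype_proportions)
  on_aag <- subtype %in% c("AAG", "mixed")
  on_gg <- subtype %in% c("GG", "mixed")
  ids <- sim_gene_ids(cfg)
  rho <- cfg$within_core_correlation

  pathway_factor <- function(on, p_on) {
    a <- cfg$activity_shift * on + cfg$activity_noise_sd * rnorm(n)
    mu <- cfg$activity_shift * p_on
    s <- sqrt(cfg$activity_shift^2 * p_on * (1 - p_on) +
                cfg$activity_noise_sd^2)
    if (s == 0) a - mu else (a - mu) / s
  }
  p_aag <- sum(cfg$subtype_proportions[c("AAG", "mixed")])
  p_gg <- sum(cfg$subtype_proportions[c("GG", "mixed")])
  f_aag <- pathway_factor(on_aag, p_aag)
  f_gg <- pathway_factor(on_gg, p_gg)

  core_block <- function(f, k) {
    eps <- matrix(rnorm(k * n), k, n)
    cfg$noise_sd * (sqrt(rho) * matrix(f, k, n, byrow = TRUE) +
                      sqrt(1 - rho) * eps)
  }
  noise_block <- function(k) cfg$noise_sd * matrix(rnorm(k * n), k, n)

  expr <- rbind(core_block(f_aag, cfg$core_size),
                noise_block(cfg$decoy_size),
                core_block(f_gg, cfg$core_size),
                noise_block(cfg$decoy_size),
                noise_block(cfg$n_background_genes))
  ## an ERBB2-like marker, reduced by one SD in the GG subtype
  erbb2 <- cfg$noise_sd * (rnorm(n) - 1.0 * (subtype == "GG"))
  expr <- rbind(expr, erbb2)
  gene_ids <- c(unlist(ids, use.names = FALSE), "ERBB2")
  baseline <- runif(length(gene_ids), 6, 12)
  expr <- expr + baseline
  dimnames(expr) <- list(gene_ids, sprintf("S%04d", seq_len(n)))

  hz <- cfg$baseline_hazard * exp(cfg$log_hr[subtype])
  event_time <- rexp(n, hz)
  tmax <- censoring_horizon(cfg$censoring_rate,
                            cfg$baseline_hazard * exp(cfg$log_hr),
                            cfg$subtype_proportions)
  cens_time <- if (is.finite(tmax)) runif(n, 0, tmax) else rep(Inf, n)
  os_time <- pmin(event_time, cens_time)
  os_event <- as.integer(event_time <= cens_time)
  dss_event <- as.integer(os_event == 1 & runif(n) < 0.85)

  her2 <- sample(c(0:3, NA), n, replace = TRUE,
                 prob = c(30, 11, 5, 5, 61) / 112)
  clinical <- data.frame(
    sample_id = colnames(expr),
    group = "GC",
    os_time = os_time, os_event = os_event,
    dss_time = os_time, dss_event = dss_event,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.4, 0.1, 0.3, 0.2)),
    grade = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    her2_ihc = her2,
    immune_subtype = sample(paste0("C", 1:6), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- list(subtype = setNames(subtype, colnames(expr)),
                aag_core = ids$aag_core, aag_decoy = ids$aag_decoy,
                gg_core = ids$gg_core, gg_decoy = ids$gg_decoy,
                erbb2_like = "ERBB2")
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Configuration for the synthetic serum metabolome
#'
#' Emulates a two-group (tumour vs healthy) untargeted serum metabolome:
#' log-normal intensities, planted differential metabolites whose raw-scale
#' group mean ratio equals the configured fold change, and block-correlated
#' metabolite modules of which one tracks the tumour samples' HER2 IHC
#' score.
#'
#' @param n_gc,n_healthy group sizes (default 112 each).
#' @param n_metabolites total metabolites (default 1300).
#' @param module_spec list of modules, each
#'   `list(size, within_correlation, trait_correlation)`; the trait
#'   correlation is the target metabolite-HER2 Pearson correlation among
#'   tumour samples and must satisfy
#'   `|trait_correlation| < sqrt(within_correlation)`.
#' @param dem_spec `list(up = list(n, fc), down = list(n, fc))` planted
#'   differential metabolites (`fc` = tumour/healthy mean ratio; defaults
#'   50 up at 1.5 and 100 down at 2/3).
#' @param lognormal_sigma SD of natural-log intensities (default 0.3).
#' @param her2_distribution probabilities over IHC scores 0..3 (default:
#'   the 30/11/5/5 split observed in a 51-patient IHC series); must sum
#'   to 1.
#' @param seed RNG seed.
#' @return A validated list of class `metabolome_sim_config`.
#' @export
metabolome_sim_config <- function(n_gc = 112, n_healthy = 112,
                                  n_metabolites = 1300,
                                  module_spec = list(
                                    list(size = 20, within_correlation = 0.7,
                                         trait_correlation = 0.5),
                                    list(size = 15, within_correlation = 0.7,
                                         trait_correlation = 0),
                                    list(size = 15, within_correlation = 0.7,
                                         trait_correlation = 0)),
                                  dem_spec = list(up = list(n = 50, fc = 1.5),
                                                  down = list(n = 100,
                                                              fc = 2 / 3)),
                                  lognormal_sigma = 0.3,
                                  her2_distribution = c(`0` = 30, `1` = 11,
                                                        `2` = 5, `3` = 5) / 51,
                                  seed = 1L) {
  cfg <- as.list(environment())
  n_dem <- sum(vapply(dem_spec, function(d) d$n %||% 0, numeric(1)))
  n_mod <- sum(vapply(module_spec, `[[`, numeric(1), "size"))
  if (n_dem + n_mod > n_metabolites)
    stop("module sizes plus planted DEMs exceed n_metabolites")
  for (d in dem_spec)
    if (!is.null(d$fc) && d$fc <= 0) stop("fold changes must be > 0")
  for (m in module_spec) {
    if (m$within_correlation <= 0 || m$within_correlation >= 1)
      stop("within_correlation must be in (0, 1)")
    if (abs(m$trait_correlation) >= sqrt(m$within_correlation))
      stop("|trait_correlation| must be < sqrt(within_correlation)")
  }
  if (abs(sum(her2_distribution) - 1) > 1e-8)
    stop("her2_distribution must sum to 1")
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be > 0")
  class(cfg) <- "metabolome_sim_config"
  cfg
}

#' Simulate a two-group serum metabolome with planted structure
#'
#' @param cfg a [metabolome_sim_config()].
#' @return A list with `abundance` (strictly positive metabolites x samples
#'   matrix, tumour samples first), `group` (factor, levels `GC`/`healthy`,
#'   aligned to columns), `clinical` (with per-tumour-sample `her2_ihc`)
#'   and `truth` (`dem_up`, `dem_down`, `module_map`, `trait_module`).
#' @export
simulate_metabolome_cohort <- function(cfg = metabolome_sim_config()) {
  stopifnot(inherits(cfg, "metabolome_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_gc + cfg$n_healthy
  is_gc <- c(rep(TRUE, cfg$n_gc), rep(FALSE, cfg$n_healthy))
  p <- cfg$n_metabolites
  met_ids <- sprintf("MET_%04d", seq_len(p))
  sample_ids <- c(sprintf("GC_%03d", seq_len(cfg$n_gc)),
                  sprintf("HC_%03d", seq_len(cfg$n_healthy)))

  scores <- as.numeric(names(cfg$her2_distribution))
  her2 <- sample(scores, cfg$n_gc, replace = TRUE,
                 prob = cfg$her2_distribution)
  h_mu <- sum(scores * cfg$her2_distribution)
  h_sd <- sqrt(sum(scores^2 * cfg$her2_distribution) - h_mu^2)
  h_z <- (her2 - h_mu) / h_sd

  mu <- runif(p, log(1e4), log(1e6))
  logx <- matrix(rnorm(p * n), p, n)  # iid residuals, filled in below

  idx <- 0
  take <- function(k) {
    out <- idx + seq_len(k)
    idx <<- idx + k
    out
  }
  up_idx <- take(cfg$dem_spec$up$n %||% 0)
  down_idx <- take(cfg$dem_spec$down$n %||% 0)
  module_map <- setNames(integer(0), character(0))
  trait_module <- NA_integer_
  for (m in seq_along(cfg$module_spec)) {
    spec <- cfg$module_spec[[m]]
    rows <- take(spec$size)
    module_map[met_ids[rows]] <- m
    w <- spec$within_correlation
    cf <- spec$trait_correlation / sqrt(w)
    if (spec$trait_correlation != 0 && is.na(trait_module)) trait_module <- m
    f <- numeric(n)
    f[is_gc] <- cf * h_z + sqrt(1 - cf^2) * rnorm(cfg$n_gc)
    f[!is_gc] <- rnorm(cfg$n_healthy)
    fk <- matrix(f, length(rows), n, byrow = TRUE)
    logx[rows, ] <- sqrt(w) * fk + sqrt(1 - w) * logx[rows, ]
  }
  logx <- mu + cfg$lognormal_sigma * logx
  if (length(up_idx))
    logx[up_idx, is_gc] <- logx[up_idx, is_gc] + log(cfg$dem_spec$up$fc)
  if (length(down_idx))
    logx[down_idx, is_gc] <- logx[down_idx, is_gc] + log(cfg$dem_spec$down$fc)

  abundance <- exp(logx)
  dimnames(abundance) <- list(met_ids, sample_ids)
  group <- factor(ifelse(is_gc, "GC", "healthy"),
                  levels = c("GC", "healthy"))
  clinical <- data.frame(
    sample_id = sample_ids,
    group = as.character(group),
    her2_ihc = c(her2, rep(NA, cfg$n_healthy)),
    stringsAsFactors = FALSE
  )
  truth <- list(dem_up = met_ids[up_idx], dem_down = met_ids[down_idx],
                module_map = module_map, trait_module = trait_module,
                her2 = setNames(her2, sample_ids[is_gc]))
  list(abundance = abundance, group = group, clinical = clinical,
       truth = truth)
}

#' Build gene sets matching a simulated expression cohort
#'
#' Emits one AAG-like and one GG-like pathway set (the planted core plus
#' decoy members) and `n_immune_sets` pairwise-disjoint placeholder immune
#' sets drawn from the background genes, mirroring the convention of
#' scoring 29 immune activity signatures per sample.
#'
#' @param cfg the [expression_sim_config()] used (gene ids are a
#'   deterministic function of it).
#' @param n_immune_sets number of immune sets (default 29).
#' @param immune_set_size genes per immune set (default 30).
#' @return Named list of gene-id vectors (GMT-writable via [write_gmt()]).
#' @export
make_gene_sets <- function(cfg = expression_sim_config(),
                           n_immune_sets = 29, immune_set_size = 30) {
  stopifnot(inherits(cfg, "subtype_sim_config"))
  ids <- sim_gene_ids(cfg)
  if (n_immune_sets * immune_set_size > cfg$n_background_genes)
    stop("requested immune sets exceed available background genes")
  set.seed(cfg$seed + 7919L)
  pool <- sample(ids$background,
                 n_immune_sets * immune_set_size)
  immune <- split(pool, rep(seq_len(n_immune_sets), each = immune_set_size))
  names(immune) <- sprintf("IMMUNE_SET_%02d", seq_len(n_immune_sets))
  sets <- c(list(KEGG_ALANINE_ASPARTATE_AND_GLUTAMATE_METABOLISM =
                   c(ids$aag_core, ids$aag_decoy),
                 KEGG_GLYCOLYSIS_GLUCONEOGENESIS =
                   c(ids$gg_core, ids$gg_decoy)),
            immune)
  sets
}
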