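#' Configuration for a synthetic PSI cohort
#'
#' Defines the study conditions the generator emulates: planted
#' correlated event modules, a tumor-versus-normal splicing shift on
#' the logit scale, bounded noisy PSI values, missing-at-random
#' entries, and survival endpoints whose hazard depends on the true
#' module scores.
#'
#' Defaults describe one desk-scale cancer cohort: 2000 events with 3
#' planted modules of 60 events, 40 tumor and 12 normal samples,
#' within-module factor loadings of 1.2 on the logit scale, a tumor
#' logit shift of 2 (about +0.3 mean PSI for mid-range events),
#' Gaussian PSI noise of 0.05, 0.2 percent missing cells, a log-hazard
#' coefficient of 1 per unit module score and 30 percent censoring.
#' Loadings are positive by default so module scores track the latent
#' factor coherently; `negative_loading_prob` plants anticorrelated
#' splicing switches.
#'
#' @param n_events Total number of splicing events.
#' @param module_sizes Integer vector of planted module sizes.
#' @param n_tumor,n_normal Sample counts per group.
#' @param loading_strength Magnitude of the per-event factor loading on
#'   the logit scale.
#' @param negative_loading_prob Probability an event loads negatively
#'   on its module factor (default 0: coherent modules).
#' @param delta Tumor shift on the logit scale, recycled per module.
#' @param noise_sd Gaussian noise added to PSI after the inverse-logit.
#' @param missing_rate Probability a cell is dropped.
#' @param beta Log-hazard coefficient per unit true module score,
#'   recycled per module.
#' @param baseline_hazard Baseline exponential hazard per day.
#' @param pfi_hazard_multiplier Baseline multiplier for the
#'   progression endpoint (progressions occur earlier than deaths).
#' @param censoring_rate Probability a subject is censored.
#' @param seed Mandatory integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_events = 2000, module_sizes = c(60, 60, 60),
                             n_tumor = 40, n_normal = 12,
                             loading_strength = 1.2,
                             negative_loading_prob = 0, delta = 2,
                             noise_sd = 0.05, missing_rate = 0.002,
                             beta = 1, baseline_hazard = 1 / 1000,
                             pfi_hazard_multiplier = 2,
                             censoring_rate = 0.3, seed) {
  if (missing(seed)) abort("synthetic_config requires an explicit seed")
  cfg <- list(
    n_events = as.integer(n_events), module_sizes = as.integer(module_sizes),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    loading_strength = loading_strength,
    negative_loading_prob = negative_loading_prob,
    delta = rep_len(delta, length(module_sizes)),
    noise_sd = noise_sd, missing_rate = missing_rate,
    beta = rep_len(beta, length(module_sizes)),
    baseline_hazard = baseline_hazard,
    pfi_hazard_multiplier = pfi_hazard_multiplier,
    censoring_rate = censoring_rate, seed = as.integer(seed)
  )
  if (sum(cfg$module_sizes) > cfg$n_events) {
    abort("module sizes must sum to at most n_events")
  }
  rates <- c(cfg$missing_rate, cfg$censoring_rate, cfg$negative_loading_prob)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$loading_strength < 0) {
    abort("noise_sd and loading_strength must be nonnegative")
  }
  if (cfg$n_tumor < 1 || cfg$n_normal < 1) abort("need >= 1 sample per group")
  structure(cfg, class = "synthetic_config")
}

# splice-class mix modeled on a large observed module's composition
SYNTH_CLASS_PROB <- c(AA = 41, AD = 36, AT = 229, ES = 210, ME = 3, RI = 191) / 710

#' Generate a synthetic PSI cohort with planted modules
#'
#' PSI values follow
#' `clamp01(inv_logit(b_e + lambda_e * z_(m(e),s) + delta_m * tumor) + eps)`
#' with per-event baseline logits `b_e ~ N(0,1)`, signed factor
#' loadings, per-module-per-sample latent factors `z ~ N(0,1)`, and
#' Gaussian noise. Cells go missing uniformly at `missing_rate`.
#' Overall-survival and progression times are exponential with hazard
#' `h0 * exp(sum_m beta_m * true_score_(m,s))`; censored subjects get a
#' uniform fraction of their latent time. Fully reproducible from the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @param module_assignment Optional integer vector (length `n_events`,
#'   0 = background) overriding the default block assignment; used by
#'   [generate_multitype()].
#' @param event_prefix Prefix for event ids (default `"ev"`).
#' @return List with `psi` (a `psi_matrix`), `clinical` (tibble for
#'   tumor samples), and `truth` (module assignment, baseline logits,
#'   loadings, latent factors, true module scores, survival
#'   parameters).
#' @export
generate_cohort <- function(config, module_assignment = NULL,
                            event_prefix = "ev") {
  cfg <- config
  set.seed(cfg$seed)
  nE <- cfg$n_events
  nT <- cfg$n_tumor
  nN <- cfg$n_normal
  nS <- nT + nN
  K <- length(cfg$module_sizes)
  if (is.null(module_assignment)) {
    module_assignment <- integer(nE)
    pos <- 0L
    for (mdx in seq_len(K)) {
      module_assignment[pos + seq_len(cfg$module_sizes[mdx])] <- mdx
      pos <- pos + cfg$module_sizes[mdx]
    }
  }
  stopifnot(length(module_assignment) == nE)

  event_id <- sprintf("%s%05d", event_prefix, seq_len(nE))
  gene_symbol <- sprintf("GENE%05d", ceiling(seq_len(nE) * 0.9))
  splice_class <- sample(names(SYNTH_CLASS_PROB), nE, replace = TRUE,
                         prob = SYNTH_CLASS_PROB)
  sample_id <- c(sprintf("T%03d", seq_len(nT)), sprintf("N%03d", seq_len(nN)))
  group <- c(rep("tumor", nT), rep("normal", nN))

  b <- stats::rnorm(nE, 0, 1)
  loading_sign <- ifelse(stats::runif(nE) < cfg$negative_loading_prob, -1, 1)
  lambda <- ifelse(module_assignment > 0,
                   cfg$loading_strength * loading_sign, 0)
  z <- matrix(stats::rnorm(max(K, 1) * nS), nrow = max(K, 1), ncol = nS)
  logit_mu <- matrix(b, nE, nS)
  is_tumor_col <- group == "tumor"
  for (mdx in seq_len(K)) {
    rows <- module_assignment == mdx
    logit_mu[rows, ] <- logit_mu[rows, ] +
      outer(lambda[rows], z[mdx, ]) +
      cfg$delta[mdx] * matrix(rep(as.numeric(is_tumor_col), each = sum(rows)),
                              nrow = sum(rows))
  }
  mu <- inv_logit(logit_mu)
  values <- clamp01(mu + matrix(stats::rnorm(nE * nS, 0, cfg$noise_sd), nE, nS))
  if (cfg$missing_rate > 0) {
    values[stats::runif(nE * nS) < cfg$missing_rate] <- NA_real_
  }

  # true module scores from the noiseless means
  true_scores <- matrix(0, nrow = max(K, 1), ncol = nT,
                        dimnames = list(NULL, sample_id[is_tumor_col]))
  for (mdx in seq_len(K)) {
    rows <- module_assignment == mdx
    ref <- rowMeans(mu[rows, !is_tumor_col, drop = FALSE])
    true_scores[mdx, ] <- colMeans(mu[rows, is_tumor_col, drop = FALSE] - ref)
  }

  lp <- if (K > 0) colSums(cfg$beta * true_scores) else rep(0, nT)
  hazard_os <- cfg$baseline_hazard * exp(lp)
  hazard_pfi <- cfg$baseline_hazard * cfg$pfi_hazard_multiplier * exp(lp)
  t_os <- stats::rexp(nT, hazard_os)
  t_pfi <- stats::rexp(nT, hazard_pfi)
  cens_os <- stats::runif(nT) < cfg$censoring_rate
  cens_pfi <- stats::runif(nT) < cfg$censoring_rate
  clinical <- tibble(
    sample_id = sample_id[is_tumor_col],
    os_time = ifelse(cens_os, stats::runif(nT) * t_os, t_os),
    os_event = as.integer(!cens_os),
    pfi_time = ifelse(cens_pfi, stats::runif(nT) * t_pfi, t_pfi),
    pfi_event = as.integer(!cens_pfi)
  )

  psi <- psi_matrix(
    values,
    events = tibble(event_id = event_id, gene_symbol = gene_symbol,
                    splice_class = splice_class, exon_descriptor = ""),
    samples = tibble(sample_id = sample_id, group = group)
  )
  truth <- list(
    module_assignment = setNames(module_assignment, event_id),
    baseline_logit = setNames(b, event_id),
    loading = setNames(lambda, event_id),
    latent = z, true_scores = true_scores,
    beta = cfg$beta, baseline_hazard = cfg$baseline_hazard,
    config = cfg
  )
  list(psi = psi, clinical = clinical, truth = truth)
}

#' Generate linked cohorts for several cancer types
#'
#' All cohorts share one event universe so modules can be applied
#' across types. Shared modules occupy the same event ids with the
#' same effect direction in every type they are planted in; each
#' type's own (private) modules occupy event blocks used by no other
#' type. Types not carrying a shared module still quantify its events
#' as unperturbed background.
#'
#' @param configs Named list of [synthetic_config()] (one per cancer
#'   type, each with its own seed). All must agree on `n_events`;
#'   `module_sizes` gives each type's private modules.
#' @param shared_modules Optional list of specs, each a list with
#'   `size`, `delta`, `beta`, and `types` (character vector of type
#'   names, or `"all"`).
#' @return Named list per type: `psi`, `clinical`, `truth`. The truth
#'   gains `shared_event_ids`, a list of event-id vectors per shared
#'   module.
#' @export
generate_multitype <- function(configs, shared_modules = NULL) {
  if (length(configs) < 2 || is.null(names(configs))) {
    abort("generate_multitype needs >= 2 named configs")
  }
  nE <- unique(vapply(configs, `[[`, integer(1), "n_events"))
  if (length(nE) != 1) abort("all configs must share n_events")
  types <- names(configs)
  shared_modules <- shared_modules %||% list()
  for (sm in shared_modules) {
    if (!all(c("size", "delta", "types") %in% names(sm))) {
      abort("each shared module needs size, delta, and types")
    }
  }
  # allocate non-overlapping event blocks: shared first, then private
  pos <- 0L
  shared_blocks <- lapply(shared_modules, function(sm) {
    blk <- pos + seq_len(sm$size)
    pos <<- pos + as.integer(sm$size)
    blk
  })
  private_blocks <- list()
  for (ty in types) {
    sizes <- configs[[ty]]$module_sizes
    private_blocks[[ty]] <- lapply(sizes, function(sz) {
      blk <- pos + seq_len(sz)
      pos <<- pos + as.integer(sz)
      blk
    })
  }
  if (pos > nE) abort("module blocks exceed n_events across types")

  out <- list()
  for (ty in types) {
    cfg <- configs[[ty]]
    applies <- vapply(shared_modules, function(sm) {
      identical(sm$types, "all") || ty %in% sm$types
    }, logical(1))
    sh <- shared_modules[applies]
    sh_blocks <- shared_blocks[applies]
    assignment <- integer(nE)
    sizes <- integer(0)
    deltas <- numeric(0)
    betas <- numeric(0)
    mdx <- 0L
    for (i in seq_along(sh)) {
      mdx <- mdx + 1L
      assignment[sh_blocks[[i]]] <- mdx
      sizes <- c(sizes, length(sh_blocks[[i]]))
      deltas <- c(deltas, sh[[i]]$delta)
      betas <- c(betas, sh[[i]]$beta %||% 0)
    }
    for (i in seq_along(private_blocks[[ty]])) {
      mdx <- mdx + 1L
      assignment[private_blocks[[ty]][[i]]] <- mdx
      sizes <- c(sizes, length(private_blocks[[ty]][[i]]))
      deltas <- c(deltas, cfg$delta[i])
      betas <- c(betas, cfg$beta[i])
    }
    cfg_ty <- cfg
    cfg_ty$module_sizes <- sizes
    cfg_ty$delta <- deltas
    cfg_ty$beta <- betas
    cohort <- generate_cohort(cfg_ty, module_assignment = assignment)
    cohort$truth$shared_event_ids <- lapply(sh_blocks, function(blk) {
      names(cohort$truth$module_assignment)[blk]
    })
    out[[ty]] <- cohort
  }
  out
}
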