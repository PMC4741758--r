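#' Configuration for the tumor/immune mixture simulator
#'
#' Defines a seeded synthetic cohort with the statistical structure the
#' immune-normalization model assumes: every biopsy is a mixture of tumor
#' cells and a latent immune fraction `phi_s` (Beta-distributed), immune-gene
#' abundance scales with `phi_s`, a latent immune-activity score `a_s` drives
#' both the expression of prognostic immune genes and the hazard of death.
#' Measurement noise is multiplicative lognormal with a scale-free CV.
#'
#' Defaults emulate a large single-cancer-type cohort: 480 patients, 2000
#' genes of which 150 form the immune block (plus one anchor and 30
#' prognostic immune genes), immune fractions around 25% (Beta(2, 6)),
#' measurement noise CV 0.15, exponential survival with median ~3 years at
#' average activity, and about 65% censoring.
#'
#' @param n_samples patients (default 480).
#' @param n_genes total genes including anchor (default 2000).
#' @param immune_block_size immune genes tracking `phi_s` only (default 150).
#' @param prognostic_immune_count immune genes whose expression also carries
#'   the activity signal `exp(gamma * a_s)` (default 30).
#' @param phi_shape1,phi_shape2 Beta parameters of the immune fraction
#'   (default 2, 6: mean 0.25).
#' @param activity_sd standard deviation of the latent activity `a_s`
#'   (default 1).
#' @param noise_cv lognormal measurement-noise coefficient of variation
#'   (default 0.15).
#' @param baseline_meanlog,baseline_sdlog lognormal distribution of per-gene
#'   baseline means (default log(500), 1.5 — a wide RSEM-like abundance
#'   range).
#' @param baseline_hazard exponential death hazard per day at `a_s = 0`
#'   (default log(2)/1200: median survival 1200 days).
#' @param beta log-hazard coefficient on `a_s` (default 0.8).
#' @param gamma log-expression coefficient of `a_s` in prognostic immune
#'   genes (default 0.5).
#' @param censoring_rate target fraction of censored patients, achieved by
#'   independent uniform censoring (default 0.65).
#' @param stage_link logit coefficient of `a_s` on the probability of
#'   advanced stage (III/IV); 0 (default) draws stage independently.
#' @param anchor anchor gene name (default `"PTPRC"`).
#' @param seed mandatory integer seed.
#' @return a validated `"sim_config"` list.
#' @export
sim_config <- function(n_samples = 480, n_genes = 2000,
                       immune_block_size = 150,
                       prognostic_immune_count = 30,
                       phi_shape1 = 2, phi_shape2 = 6,
                       activity_sd = 1, noise_cv = 0.15,
                       baseline_meanlog = log(500), baseline_sdlog = 1.5,
                       baseline_hazard = log(2) / 1200, beta = 0.8,
                       gamma = 0.5, censoring_rate = 0.65,
                       stage_link = 0, anchor = "PTPRC", seed) {
  if (missing(seed) || is.null(seed)) stopf("a seed is mandatory")
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              immune_block_size = as.integer(immune_block_size),
              prognostic_immune_count = as.integer(prognostic_immune_count),
              phi_shape1 = phi_shape1, phi_shape2 = phi_shape2,
              activity_sd = activity_sd, noise_cv = noise_cv,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              baseline_hazard = baseline_hazard, beta = beta, gamma = gamma,
              censoring_rate = censoring_rate, stage_link = stage_link,
              anchor = anchor, seed = as.integer(seed))
  if (cfg$n_samples < 6) stopf("n_samples must be >= 6")
  if (cfg$immune_block_size + cfg$prognostic_immune_count + 1 > cfg$n_genes) {
    stopf("immune block + prognostic genes + anchor exceed n_genes")
  }
  if (cfg$phi_shape1 <= 0 || cfg$phi_shape2 <= 0) {
    stopf("Beta parameters must be positive")
  }
  if (cfg$activity_sd < 0 || cfg$noise_cv < 0 || cfg$baseline_sdlog < 0) {
    stopf("variance parameters must be >= 0")
  }
  if (cfg$baseline_hazard <= 0) stopf("baseline hazard must be positive")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stopf("censoring_rate must lie in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

# lognormal with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a tumor/immune mixture cohort
#'
#' Draws a seeded cohort under the generative model of [sim_config()]:
#' expression `X(g, s) = m_g * w(g, s) * eps(g, s)` with lognormal noise
#' `eps` (mean 1, CV `noise_cv`), where the mixing weight `w` is `phi_s` for
#' the anchor and immune genes, `phi_s * exp(gamma * a_s)` for prognostic
#' immune genes, and 1 for tumor-intrinsic genes. Death times are
#' exponential with hazard `baseline_hazard * exp(beta * a_s)`; censoring is
#' independent uniform, calibrated on the drawn death times to the target
#' censored fraction. Age and gender are independent; stage is independent
#' unless `stage_link` ties advanced stage to `a_s`.
#'
#' @param config a [sim_config()] object.
#' @return a `"sim_cohort"` list: `expr` (expression matrix), `clinical`
#'   (clinical table), `truth` (per-sample `phi` and `activity`, per-gene
#'   `gene_class` in \{anchor, immune, prognostic_immune, tumor\}, and the
#'   `config`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must come from sim_config()")
  with_seed(config$seed, {
    n <- config$n_samples
    g <- config$n_genes
    sample_ids <- sprintf("S%04d", seq_len(n))
    n_imm <- config$immune_block_size
    n_prg <- config$prognostic_immune_count
    n_tum <- g - 1 - n_imm - n_prg
    gene_ids <- c(config$anchor,
                  sprintf("IMM%04d", seq_len(n_imm)),
                  sprintf("PRG%04d", seq_len(n_prg)),
                  sprintf("TUM%04d", seq_len(n_tum)))
    gene_class <- c("anchor", rep("immune", n_imm),
                    rep("prognostic_immune", n_prg), rep("tumor", n_tum))
    names(gene_class) <- gene_ids

    phi <- stats::rbeta(n, config$phi_shape1, config$phi_shape2)
    activity <- stats::rnorm(n, 0, config$activity_sd)
    m <- stats::rlnorm(g, config$baseline_meanlog, config$baseline_sdlog)

    w <- matrix(1, nrow = g, ncol = n)
    imm_rows <- gene_class %in% c("anchor", "immune")
    w[imm_rows, ] <- matrix(phi, nrow = sum(imm_rows), ncol = n, byrow = TRUE)
    prg_rows <- gene_class == "prognostic_immune"
    if (any(prg_rows)) {
      w[prg_rows, ] <- matrix(phi * exp(config$gamma * activity),
                              nrow = sum(prg_rows), ncol = n, byrow = TRUE)
    }
    eps <- matrix(rlnorm_cv(g * n, config$noise_cv), nrow = g, ncol = n)
    expr <- m * w * eps
    dimnames(expr) <- list(gene_ids, sample_ids)

    death <- stats::rexp(n, rate = config$baseline_hazard *
                           exp(config$beta * activity))
    if (config$censoring_rate > 0) {
      # calibrate the uniform censoring horizon on the drawn death times:
      # expected censored fraction = mean(min(T/cmax, 1))
      target <- config$censoring_rate
      fr <- function(cmax) mean(pmin(death / cmax, 1)) - target
      upper <- max(death) / target + 1
      cmax <- stats::uniroot(fr, lower = min(death) * 1e-6,
                             upper = upper)$root
      cens <- stats::runif(n, 0, cmax)
    } else {
      cens <- rep(Inf, n)
    }
    event <- as.integer(death <= cens)
    os_time <- pmin(death, cens)

    age <- round(stats::rnorm(n, 60, 10))
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (config$stage_link != 0) {
      adv <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.45) +
                                                 config$stage_link * activity))
    } else {
      adv <- stats::rbinom(n, 1, 0.45)
    }
    stage <- ifelse(adv == 1,
                    sample(c("III", "IV"), n, replace = TRUE),
                    sample(c("I", "II"), n, replace = TRUE,
                           prob = c(0.8, 0.2)))

    clinical <- data.frame(sample_id = sample_ids, os_time = os_time,
                           event = event, age = age, gender = gender,
                           stage = stage, stringsAsFactors = FALSE)
    structure(list(expr = as_expression_matrix(expr), clinical = clinical,
                   truth = list(phi = stats::setNames(phi, sample_ids),
                                activity = stats::setNames(activity,
                                                           sample_ids),
                                gene_class = gene_class,
                                config = config)),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cls <- table(x$truth$gene_class)
  cat(sprintf("Simulated tumor/immune cohort: %d genes x %d samples (seed %d)\n",
              nrow(x$expr), ncol(x$expr), x$truth$config$seed))
  cat(sprintf("  gene classes: %s\n",
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  cat(sprintf("  events: %d/%d (censoring %.0f%%)\n",
              sum(x$clinical$event), nrow(x$clinical),
              100 * mean(x$clinical$event == 0)))
  invisible(x)
}
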