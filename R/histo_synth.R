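with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

reference_gp4_values <- function() {
  c("<5", "<5", "10", "60", "5", "0", "15", "30", "20", "<5", "<5", "50", "0")
}

#' Generative parameters for synthetic histology and expression tables
#'
#' One configuration object holds every default of the synthetic-data layer:
#' per-group cell-count distributions, marker positivity probabilities per
#' compartment, negative-binomial mRNA copy means, and log-normal expression
#' shifts for the RSEM-like tables. The groups are `low_gp4` / `high_gp4`
#' (lesion level, percent Gleason pattern 4 below or above 10) and
#' `GP3` / `GP4` / `GP5` (single-gland level).
#'
#' Defaults are calibrated to the qualitative direction pattern reported for
#' prostate cancer - epithelial-dominant MCT1, stromal-dominant MCT4,
#' higher LDHA / lower LDHB / lower PDHA1 and more nuclear HIF-1alpha
#' positivity with increasing aggressiveness, a flat SLC16A1 between GP3 and
#' GP4 - never to unpublished group means. Override any entry via `...`
#' using nested lists (merged with [utils::modifyList()]).
#'
#' @param seed Default seed stored with the config (used when a generator is
#'   called without its own seed).
#' @param ... Named overrides merged into the default list.
#' @return An object of class `"effect_config"`.
#' @export
effect_config <- function(seed = NULL, ...) {
  grp <- function(n_epi, n_str, mct1_e, mct1_s, mct4_e, mct4_s, hif_e, hif_s,
                  ldha_e, ldhb_e, pdha1_e, ldha_s, ldhb_s, pdha1_s) {
    list(
      n_epi_mean = n_epi, n_str_mean = n_str, cells_dispersion = 20,
      markers = list(
        MCT1 = list(epithelial = mct1_e, stromal = mct1_s),
        MCT4 = list(epithelial = mct4_e, stromal = mct4_s),
        HIF1A_nuclear = list(epithelial = hif_e, stromal = hif_s)),
      category_split = c(weak = 0.5, moderate = 0.3, strong = 0.2),
      genes = list(
        LDHA = list(epithelial = ldha_e, stromal = ldha_s),
        LDHB = list(epithelial = ldhb_e, stromal = ldhb_s),
        PDHA1 = list(epithelial = pdha1_e, stromal = pdha1_s)),
      genes_dispersion = 2)
  }
  defaults <- list(
    seed = seed,
    groups = list(
      low_gp4  = grp(600, 400, 0.55, 0.15, 0.12, 0.60, 0.05, 0.05,
                     6, 8, 5, 2.5, 3, 2),
      high_gp4 = grp(800, 350, 0.50, 0.15, 0.32, 0.62, 0.08, 0.06,
                     10, 5, 3, 2.5, 3, 2),
      GP3      = grp(600, 400, 0.55, 0.15, 0.12, 0.60, 0.05, 0.05,
                     6, 8, 5, 2.5, 3, 2),
      GP4      = grp(700, 380, 0.52, 0.16, 0.18, 0.62, 0.07, 0.05,
                     7, 7, 4.5, 2.5, 3, 2),
      GP5      = grp(900, 320, 0.70, 0.30, 0.48, 0.72, 0.25, 0.20,
                     14, 4, 2, 3.5, 2.5, 1.5)),
    expression = list(
      baseline_log2 = c(SLC16A1 = 10, SLC16A3 = 9, LDHA = 12, LDHB = 11),
      sd_log2 = 0.8,
      shifts = list(
        GP3 = c(SLC16A1 = 0, SLC16A3 = 0, LDHA = 0, LDHB = 0),
        GP4 = c(SLC16A1 = 0, SLC16A3 = 0.6, LDHA = 0.6, LDHB = -0.6),
        GP5 = c(SLC16A1 = 0.2, SLC16A3 = 1.0, LDHA = 0.8, LDHB = -1.0))),
    cohort = list(
      kpl_range = c(0.003, 0.018),
      gp4_weight = 0.5,
      amplitude_sd_log = 0.25,
      target_pyruvate_snr = 40,
      lesion_radius = 3,
      n_cells = 800)
  )
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = "effect_config")
}

stain_levels <- c("negative", "weak", "moderate", "strong")

#' Generate a synthetic per-cell histology table for one ROI
#'
#' Draws epithelial and stromal cells with marker staining categories
#' (multinomial: positive with the configured probability, then weak /
#' moderate / strong) and per-gene mRNA copy counts (negative binomial with
#' configured means; RNAscope-style counts are overdispersed, Poisson being
#' the infinite-dispersion limit).
#'
#' @param config An [effect_config()].
#' @param group Group label: one of `low_gp4`, `high_gp4`, `GP3`, `GP4`,
#'   `GP5`.
#' @param n_cells Total number of cells; `NULL` draws epithelial and stromal
#'   counts from the configured distributions.
#' @param seed Integer seed, or `NULL` (falls back to `config$seed`).
#' @param lesion_id Optional label stored on the result.
#' @param overrides Optional named list of group-parameter overrides for this
#'   draw (merged into the group config).
#' @return A `"cell_table"` data frame: `compartment`, staining factors
#'   `MCT1`, `MCT4`, `HIF1A_nuclear`, integer copy counts `LDHA`, `LDHB`,
#'   `PDHA1`; attributes `group` and `lesion_id`. Always contains at least
#'   one cell of each compartment.
#' @export
generate_cell_table <- function(config, group, n_cells = NULL, seed = NULL,
                                lesion_id = NULL, overrides = NULL) {
  if (!group %in% names(config$groups))
    stop("invalid group label: ", group)
  g <- config$groups[[group]]
  if (!is.null(overrides)) g <- utils::modifyList(g, overrides)
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    if (is.null(n_cells)) {
      n_epi <- stats::rnbinom(1, size = g$cells_dispersion, mu = g$n_epi_mean)
      n_str <- stats::rnbinom(1, size = g$cells_dispersion, mu = g$n_str_mean)
    } else {
      frac <- g$n_epi_mean / (g$n_epi_mean + g$n_str_mean)
      n_epi <- round(n_cells * frac)
      n_str <- n_cells - n_epi
    }
    n_epi <- max(1L, n_epi)
    n_str <- max(1L, n_str)
    compartment <- factor(rep(c("epithelial", "stromal"), c(n_epi, n_str)),
                          levels = c("epithelial", "stromal"))
    n <- n_epi + n_str
    tab <- data.frame(compartment = compartment)
    for (mk in names(g$markers)) {
      p <- ifelse(compartment == "epithelial",
                  g$markers[[mk]]$epithelial, g$markers[[mk]]$stromal)
      pos <- stats::runif(n) < p
      cat_ <- rep("negative", n)
      if (any(pos))
        cat_[pos] <- sample(names(g$category_split), sum(pos),
                            replace = TRUE, prob = g$category_split)
      tab[[mk]] <- factor(cat_, levels = stain_levels)
    }
    for (gn in names(g$genes)) {
      mu <- ifelse(compartment == "epithelial",
                   g$genes[[gn]]$epithelial, g$genes[[gn]]$stromal)
      tab[[gn]] <- stats::rnbinom(n, size = g$genes_dispersion, mu = mu)
    }
    structure(tab, class = c("cell_table", "data.frame"),
              group = group, lesion_id = lesion_id)
  })
}

#' Generate an RSEM-like expression table grouped by primary Gleason pattern
#'
#' Per-gene log-normal values: `log2(RSEM)` is Gaussian with a per-group
#' shift added to the gene baseline. Default group sizes mirror a large
#' prostatectomy cohort (197 / 250 / 50 primary GP3 / GP4 / GP5 tumours).
#'
#' @param config An [effect_config()].
#' @param group_sizes Named integer vector over `GP3`, `GP4`, `GP5`
#'   (each >= 2).
#' @param seed Integer seed, or `NULL`.
#' @return Data frame with `sample`, `primary_gp` and one RSEM-scale column
#'   per gene.
#' @export
generate_expression_table <- function(config,
                                      group_sizes = c(GP3 = 197, GP4 = 250,
                                                      GP5 = 50),
                                      seed = NULL) {
  if (any(group_sizes < 2)) stop("group sizes must be >= 2")
  ex <- config$expression
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    gp <- rep(names(group_sizes), group_sizes)
    out <- data.frame(sample = sprintf("S%04d", seq_along(gp)),
                      primary_gp = factor(gp, levels = c("GP3", "GP4", "GP5")))
    for (gene in names(ex$baseline_log2)) {
      shift <- vapply(gp, function(g) ex$shifts[[g]][[gene]], 0)
      out[[gene]] <- 2^stats::rnorm(length(gp),
                                    ex$baseline_log2[[gene]] + shift,
                                    ex$sd_log2)
    }
    out
  })
}

#' Generate a linked synthetic cohort: imaging, kinetics and histology
#'
#' Builds `n_lesions` tumours whose ground-truth kinetics, epithelial cell
#' counts, combined epithelial LDH expression and epithelium-to-stroma MCT4
#' ratio are jointly driven by a latent per-lesion aggressiveness variable
#' through a Gaussian copula; `corr` sets the strength of that coupling
#' (0 = independent metrics, values near 1 = strongly rank-correlated).
#' The latent aggressiveness itself is tied (with weight
#' `config$cohort$gp4_weight`) to the lesion's percent Gleason pattern 4, so
#' the cohort reproduces the aggressiveness-dependent structure of a
#' 13-tumour hyperpolarised 13C study. Ground-truth kPL values span the
#' configured range (default 0.003-0.018 1/s).
#'
#' With `imaging = TRUE`, each lesion gets a digital phantom that is
#' simulated, noised (Rician) and quantified end-to-end
#' ([quantify_lesion()]): lactate / pyruvate / total-carbon SNR and voxelwise
#' mean kPL are measured, not copied from the truth. With `imaging = FALSE`
#' the lactate and pyruvate SNR columns are computed from the analytic
#' noiseless ROI curves plus sampling noise - a fast path for large-n
#' calibration studies that bypasses the voxel pipeline.
#'
#' @param config An [effect_config()].
#' @param n_lesions Number of tumours (>= 2).
#' @param gp4_distribution Character/numeric vector of %GP4 values (censored
#'   entries as `"<5"`); defaults to the 13 printed cohort values, sampled
#'   with replacement when `n_lesions` differs from its length.
#' @param corr Copula coupling in [0, 1).
#' @param seed Integer seed, or `NULL`.
#' @param imaging Run the full voxel pipeline (default) or the fast path.
#' @param schedule Acquisition schedule for the phantoms.
#' @return List of class `"synthetic_cohort"`: `cohort` (one row per lesion
#'   with imaging metrics, histology metrics and ground-truth columns),
#'   `cell_tables` (list of `"cell_table"`), and `phantoms` (list, when
#'   `imaging = TRUE`).
#' @export
generate_cohort <- function(config = effect_config(), n_lesions = 13,
                            gp4_distribution = NULL, corr = 0.7,
                            seed = NULL, imaging = TRUE,
                            schedule = acquisition_schedule()) {
  if (n_lesions < 2) stop("n_lesions must be >= 2")
  if (corr < 0 || corr >= 1) stop("corr must lie in [0, 1)")
  if (is.null(seed)) seed <- config$seed
  cc <- config$cohort
  with_seed(seed, {
    if (is.null(gp4_distribution)) {
      gp4_distribution <- if (n_lesions == 13) reference_gp4_values()
        else sample(reference_gp4_values(), n_lesions, replace = TRUE)
    }
    if (length(gp4_distribution) != n_lesions)
      stop("gp4_distribution length must equal n_lesions")
    gp4 <- gp4_numeric(gp4_distribution)
    if (stats::var(gp4$value) == 0) stop("degenerate %GP4 distribution")

    # latent aggressiveness: normal-scores of %GP4 blended with noise
    w <- cc$gp4_weight
    ns <- stats::qnorm((rank(gp4$value, ties.method = "average") - 0.375) /
                       (n_lesions + 0.25))
    z <- sqrt(w) * ns / stats::sd(ns) + sqrt(1 - w) * stats::rnorm(n_lesions)
    latent <- function() corr * z + sqrt(1 - corr^2) * stats::rnorm(n_lesions)
    u_sig <- latent()   # drives kPL (and thus lactate signal)
    u_amp <- latent()   # drives bolus amplitude (perfusion)
    u_epi <- latent()   # drives epithelial cell count
    u_ldh <- latent()   # drives epithelial LDHA+LDHB copy means
    u_mct <- latent()   # drives epithelial MCT4 positivity

    kpl_true <- cc$kpl_range[1] +
      diff(cc$kpl_range) * stats::pnorm(u_sig)
    amplitude <- exp(cc$amplitude_sd_log * u_amp)
    group <- ifelse(gp4$value > 10, "high_gp4", "low_gp4")

    cell_seeds <- sample.int(.Machine$integer.max, n_lesions)
    img_seeds <- sample.int(.Machine$integer.max, n_lesions)

    cell_tables <- vector("list", n_lesions)
    hist_rows <- vector("list", n_lesions)
    for (i in seq_len(n_lesions)) {
      g <- config$groups[[group[i]]]
      ovr <- list(
        n_epi_mean = g$n_epi_mean * exp(0.35 * u_epi[i]),
        genes = list(
          LDHA = list(epithelial = g$genes$LDHA$epithelial * exp(0.3 * u_ldh[i])),
          LDHB = list(epithelial = g$genes$LDHB$epithelial * exp(0.3 * u_ldh[i]))),
        markers = list(
          MCT4 = list(epithelial = stats::plogis(
            stats::qlogis(g$markers$MCT4$epithelial) + 0.8 * u_mct[i]))))
      cell_tables[[i]] <- generate_cell_table(
        config, group[i], seed = cell_seeds[i], lesion_id = i,
        overrides = ovr)
      hist_rows[[i]] <- as.data.frame(compartment_summary(cell_tables[[i]]))
    }
    hist_df <- do.call(rbind, hist_rows)

    # imaging chain -----------------------------------------------------
    unit_curve <- simulate_voxel_curves(mean(cc$kpl_range), schedule,
                                        bolus_input())
    if (imaging) {
      dims <- schedule$matrix_size
      noise_roi <- default_noise_roi(dims)
      lesion_mask <- disc_mask(dims, centre = (dims + 1) / 2,
                               radius = cc$lesion_radius)
      # amplitude scale mapping summed pyruvate signal to the target SNR:
      # summed Rayleigh background sd ~ sigma * sqrt((2 - pi/2) * n_frames)
      sigma <- 1
      sd_sum <- sigma * sqrt((2 - pi / 2) * schedule$n_frames)
      a0 <- cc$target_pyruvate_snr * sqrt(2) * sd_sum /
        sum(unit_curve$signal_pyruvate)
      img <- vector("list", n_lesions)
      met_rows <- vector("list", n_lesions)
      for (i in seq_len(n_lesions)) {
        ph <- phantom(dims, lesions = list(
          phantom_lesion(lesion_mask, kpl_true[i],
                         amplitude = a0 * amplitude[i])))
        ser <- simulate_dynamic_series(ph, schedule)
        noisy <- add_noise(ser, sigma, seed = img_seeds[i])
        q <- quantify_lesion(noisy, lesion_mask, noise_roi)
        img[[i]] <- ph
        met_rows[[i]] <- as.data.frame(q)
      }
      met_df <- do.call(rbind, met_rows)
      phantoms <- img
    } else {
      # analytic fast path: noiseless ROI curves, sampling noise added
      sd_sum <- sqrt((2 - pi / 2) * schedule$n_frames)
      a0 <- cc$target_pyruvate_snr * sqrt(2) * sd_sum /
        sum(unit_curve$signal_pyruvate)
      n_vox <- sum(disc_mask(schedule$matrix_size,
                             (schedule$matrix_size + 1) / 2, cc$lesion_radius))
      lac <- pyr <- numeric(n_lesions)
      for (i in seq_len(n_lesions)) {
        cv <- simulate_voxel_curves(kpl_true[i], schedule, bolus_input())
        scale_i <- a0 * amplitude[i] / (sqrt(2) * sd_sum)
        pyr[i] <- scale_i * sum(cv$signal_pyruvate) +
          stats::rnorm(1, 0, 1 / sqrt(n_vox))
        lac[i] <- scale_i * sum(cv$signal_lactate) +
          stats::rnorm(1, 0, 1 / sqrt(n_vox))
      }
      met_df <- data.frame(lactateSNR = lac, pyruvateSNR = pyr,
                           totalCarbonSNR = lac + pyr, meanKPL = kpl_true)
      phantoms <- NULL
    }

    cohort <- data.frame(
      Tumour = seq_len(n_lesions),
      pctGP4 = gp4$value,
      pctGP4_censored = gp4$censored,
      ISUP = ifelse(gp4$value == 0, 1L, ifelse(gp4$value >= 50, 3L, 2L)),
      group = factor(group, levels = c("low_gp4", "high_gp4")),
      met_df,
      hist_df,
      kpl_true = kpl_true,
      amplitude = amplitude,
      row.names = NULL)
    structure(list(cohort = cohort, cell_tables = cell_tables,
                   phantoms = phantoms, corr = corr, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d lesions, corr = %g, %s imaging\n",
              nrow(x$cohort), x$corr,
              if (is.null(x$phantoms)) "without" else "with"))
  invisible(x)
}
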