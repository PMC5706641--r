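#' Run the progressive-saturation T1 study
#'
#' End-to-end analysis of the intrinsic-T1 experiment: each subject's
#' magnetization-transfer series is normalized to its own Boltzmann
#' reference, the normalized series are averaged across subjects at each
#' saturation time, and the group-averaged curves are fitted with
#' [fit_progressive()] for PCr and Pi (the group-average approach of the
#' original analysis).  Per-subject fits are returned alongside, so either
#' mode of inference is available; with a single subject the two coincide.
#'
#' @param series_list list of `mt_series` data frames, one per subject
#'   (e.g. from [generate_mt_series()] or [read_mt_series()]).  All series
#'   must share the saturation-time grid.
#' @return a `progressive_report`: list with `group` (list of
#'   `kinetic_estimate` for PCr and Pi), `per_subject` (data frame of
#'   per-subject estimates), `n_subjects`, and the averaged normalized
#'   series in `group_series`.
#' @examples
#' net <- exchange_network(k1 = 0.37, k2 = 0.19)
#' sims <- lapply(1:3, function(i)
#'   generate_mt_series(net, noise_sd = 0, seed = i))
#' rep <- run_progressive_study(sims)
#' rep$group$PCr$T1int
#' @export
run_progressive_study <- function(series_list) {
  if (inherits(series_list, "data.frame")) series_list <- list(series_list)
  if (!length(series_list)) stop("need at least one subject", call. = FALSE)
  grids <- lapply(series_list, function(s) sort(s$t_sat_s))
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stop("all subjects must share the saturation-time grid", call. = FALSE)

  normalize <- function(s) {
    iref <- which(s$t_sat_s == 0)
    s$area_PCr <- s$area_PCr / mean(s$area_PCr[iref])
    s$area_Pi <- s$area_Pi / mean(s$area_Pi[iref])
    s$area_gATP <- s$area_gATP / mean(s$area_gATP[iref])
    s[order(s$t_sat_s), ]
  }
  norm <- lapply(series_list, normalize)
  avg <- norm[[1]]
  for (col in c("area_PCr", "area_Pi", "area_gATP")) {
    avg[[col]] <- rowMeans(vapply(norm, `[[`, numeric(nrow(avg)), col))
  }
  group <- list(PCr = fit_progressive(avg, "PCr"),
                Pi = fit_progressive(avg, "Pi"))

  per_subject <- do.call(rbind, lapply(seq_along(norm), function(i) {
    do.call(rbind, lapply(c("PCr", "Pi"), function(p) {
      f <- tryCatch(suppressWarnings(fit_progressive(norm[[i]], p)),
                    error = function(e) NULL)
      data.frame(subject = i, pool = p,
                 k = if (is.null(f)) NA_real_ else f$k,
                 T1int = if (is.null(f)) NA_real_ else f$T1int,
                 T1app = if (is.null(f)) NA_real_ else f$T1app,
                 r_squared = if (is.null(f)) NA_real_ else f$r_squared)
    }))
  }))
  out <- list(group = group, per_subject = per_subject,
              n_subjects = length(series_list), group_series = avg)
  class(out) <- "progressive_report"
  out
}

#' @export
print.progressive_report <- function(x, ...) {
  cat(sprintf("Progressive saturation study, %d subject(s); group fit:\n",
              x$n_subjects))
  for (p in c("PCr", "Pi")) {
    f <- x$group[[p]]
    cat(sprintf("  %-3s k = %.3f /s  T1int = %.2f s  T1app = %.2f s  R^2 = %.3f\n",
                p, f$k, f$T1int, f$T1app, f$r_squared))
  }
  invisible(x)
}

#' The five block contrasts of the functional paradigm
#'
#' @return named list; each element has `a` (test blocks) and `b`
#'   (reference blocks); percent change is `(a - b)/b` per subject, with
#'   multi-block sides averaged within subject first.
#' @export
default_contrasts <- function() {
  list(ON1_vs_OFF1 = list(a = "ON1", b = "OFF1"),
       ON2_vs_OFF2 = list(a = "ON2", b = "OFF2"),
       OFF2_vs_OFF1 = list(a = "OFF2", b = "OFF1"),
       ON2_vs_ON1 = list(a = "ON2", b = "ON1"),
       ON_vs_OFF = list(a = c("ON1", "ON2"), b = c("OFF1", "OFF2")))
}

#' Paired block statistics
#'
#' For a blocks-by-subjects matrix of a per-block quantity, computes each
#' contrast's subject-wise percent change (per-subject first, then
#' averaged, which is how "x% +/- y%" group changes are reported) and a
#' two-sided paired t-test on the block values.  Subjects with a zero
#' reference value are excluded from that contrast with a warning.
#'
#' @param values numeric matrix, rows named `OFF1`, `ON1`, `OFF2`, `ON2`,
#'   columns = subjects.
#' @param contrasts list as from [default_contrasts()].
#' @param holm logical; add Holm-adjusted p-values across the contrasts
#'   (off by default, mirroring the uncorrected original analysis).
#' @return a `group_stats` data frame: contrast, n, mean and sd of the
#'   subject-wise percent change, t statistic, df, p value.
#' @examples
#' v <- rbind(OFF1 = c(0.30, 0.40), ON1 = c(0.36, 0.44),
#'            OFF2 = c(0.30, 0.40), ON2 = c(0.36, 0.44))
#' block_statistics(v)[1, ]  # +15% +/- 7.1%
#' @export
block_statistics <- function(values, contrasts = default_contrasts(),
                             holm = FALSE) {
  stopifnot(is.matrix(values),
            all(c("OFF1", "ON1", "OFF2", "ON2") %in% rownames(values)))
  rows <- lapply(names(contrasts), function(cn) {
    ct <- contrasts[[cn]]
    a <- colMeans(values[ct$a, , drop = FALSE])
    b <- colMeans(values[ct$b, , drop = FALSE])
    ok <- b != 0
    if (any(!ok))
      warning(sum(!ok), " subject(s) excluded from ", cn,
              " (zero reference value)", call. = FALSE)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 2)
      return(data.frame(contrast = cn, n = n, mean_pct_change = NA_real_,
                        sd_pct_change = NA_real_, t = NA_real_,
                        df = NA_real_, p = NA_real_))
    pct <- 100 * (a - b) / b
    d <- a - b
    if (stats::sd(d) == 0) {
      tval <- if (all(d == 0)) 0 else Inf
      pval <- if (all(d == 0)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(contrast = cn, n = n, mean_pct_change = mean(pct),
               sd_pct_change = stats::sd(pct), t = tval, df = n - 1,
               p = pval)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Run the functional steady-state saturation study
#'
#' Computes, for every subject and block, the forward rate constants from
#' the (Boltzmann, steady-state) area pair via [steady_state_rate()] with
#' the supplied intrinsic T1 values (measured at rest and assumed
#' unchanged during activation), the PCr/gamma-ATP, Pi/gamma-ATP and
#' NAD(H)/gamma-ATP ratios from the unsaturated scan, the concentrations
#' and forward fluxes, and the intracellular pH from the Pi-PCr shift.
#' Group contrasts are then evaluated with [block_statistics()].
#'
#' @param study a `functional_study` data frame (see
#'   [generate_functional_study()]); any data frame with the same columns
#'   works.
#' @param T1_PCr,T1_Pi intrinsic T1 values (s), typically from
#'   [run_progressive_study()].
#' @param atp_conc assumed ATP concentration (mM).
#' @param tissue_density brain tissue density (g/mL).
#' @param calib pH calibration, see [ph_calibration()].
#' @param contrasts contrast list, see [default_contrasts()].
#' @param holm logical; Holm-adjust p values across contrasts.
#' @return a `functional_report`: list with `blocks` (per subject x block
#'   data frame of class `block_result`: k1, k2, ratios, concentrations,
#'   fluxes in both unit systems, pH, negative-rate flags), `stats` (named
#'   list of `group_stats` tables for k1, k2, ratios, concentrations and
#'   pH), `T1_PCr`, `T1_Pi`, and the pH calibration used.
#' @examples
#' study <- generate_functional_study(n_subjects = 4, noise_sd = 0, seed = 2,
#'   truth = functional_truth(k1_block_sd = 0, k2_block_sd = 0))
#' rep <- run_functional_study(study)
#' rep$stats$k1
#' @export
run_functional_study <- function(study, T1_PCr = 5.1, T1_Pi = 3.0,
                                 atp_conc = 3, tissue_density = 1.1,
                                 calib = ph_calibration(),
                                 contrasts = default_contrasts(),
                                 holm = FALSE) {
  need <- c("subject", "label", "area_PCr_ref", "area_Pi_ref",
            "area_gATP_ref", "area_PCr_sat", "area_Pi_sat")
  if (!all(need %in% names(study)))
    stop("study must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  labs <- c("OFF1", "ON1", "OFF2", "ON2")
  for (s in unique(study$subject)) {
    if (!setequal(study$label[study$subject == s], labs))
      stop("paradigm error: subject ", s,
           " does not have the four blocks OFF1, ON1, OFF2, ON2",
           call. = FALSE)
  }

  k1 <- steady_state_rate(study$area_PCr_ref, study$area_PCr_sat, T1_PCr)
  k2 <- steady_state_rate(study$area_Pi_ref, study$area_Pi_sat, T1_Pi)
  blocks <- data.frame(
    subject = study$subject, label = study$label,
    k1 = as.numeric(k1), k2 = as.numeric(k2),
    k1_negative = attr(k1, "negative"), k2_negative = attr(k2, "negative"),
    PCr_gATP = study$area_PCr_ref / study$area_gATP_ref,
    Pi_gATP = study$area_Pi_ref / study$area_gATP_ref)
  blocks$NAD_gATP <- if ("area_NAD_ref" %in% names(study))
    study$area_NAD_ref / study$area_gATP_ref else NA_real_
  blocks$conc_PCr <- concentration_from_ratio(pmax(blocks$PCr_gATP, 0),
                                              atp_conc)
  blocks$conc_Pi <- concentration_from_ratio(pmax(blocks$Pi_gATP, 0),
                                             atp_conc)
  blocks$flux_CK_mM_s <- blocks$k1 * blocks$conc_PCr
  blocks$flux_CK_umol_g_min <- flux_to_umol_g_min(blocks$flux_CK_mM_s,
                                                  tissue_density)
  blocks$flux_ATPase_mM_s <- blocks$k2 * blocks$conc_Pi
  blocks$flux_ATPase_umol_g_min <-
    flux_to_umol_g_min(blocks$flux_ATPase_mM_s, tissue_density)
  blocks$pH <- if ("delta_Pi_ppm" %in% names(study))
    ph_from_shift(study$delta_Pi_ppm, calib) else NA_real_
  class(blocks) <- c("block_result", "data.frame")

  if (any(blocks$k1_negative | blocks$k2_negative))
    warning("negative steady-state rate estimate(s) retained and flagged",
            call. = FALSE)

  measures <- c("k1", "k2", "PCr_gATP", "Pi_gATP", "NAD_gATP",
                "conc_PCr", "conc_Pi", "flux_CK_mM_s", "flux_ATPase_mM_s",
                "pH")
  stats_list <- lapply(measures, function(m) {
    if (all(is.na(blocks[[m]]))) return(NULL)
    v <- matrix(NA_real_, 4, length(unique(blocks$subject)),
                dimnames = list(labs, NULL))
    for (i in seq_len(nrow(blocks)))
      v[blocks$label[i], blocks$subject[i]] <- blocks[[m]][i]
    block_statistics(v, contrasts, holm = holm)
  })
  names(stats_list) <- measures
  stats_list <- Filter(Negate(is.null), stats_list)

  out <- list(blocks = blocks, stats = stats_list,
              T1_PCr = T1_PCr, T1_Pi = T1_Pi, atp_conc = atp_conc,
              tissue_density = tissue_density, ph_calibration = calib)
  class(out) <- "functional_report"
  out
}

#' @export
print.functional_report <- function(x, ...) {
  cat("Functional 31P MT study:",
      length(unique(x$blocks$subject)), "subjects\n")
  agg <- stats::aggregate(cbind(k1, k2, PCr_gATP, Pi_gATP, pH) ~ label,
                          data = x$blocks, FUN = mean)
  agg <- agg[match(c("OFF1", "ON1", "OFF2", "ON2"), agg$label), ]
  print(agg, digits = 3, row.names = FALSE)
  cat("k1 contrasts:\n")
  print(x$stats$k1, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report as flat JSON key-value pairs
#'
#' Serializes a `kinetic_estimate`, `progressive_report` or
#' `functional_report` to a flat JSON object (scalars and small arrays
#' only), including the calibration constants in effect, so results can be
#' consumed by other tools.
#'
#' @param x report object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  flat <- if (inherits(x, "kinetic_estimate")) {
    list(pool = x$pool, k_per_s = x$k, T1int_s = x$T1int,
         T1app_s = x$T1app, r_squared = x$r_squared,
         n_points = x$n_points, t1_identifiable = x$t1_identifiable)
  } else if (inherits(x, "progressive_report")) {
    list(n_subjects = x$n_subjects,
         k1_per_s = x$group$PCr$k, T1int_PCr_s = x$group$PCr$T1int,
         T1app_PCr_s = x$group$PCr$T1app, r2_PCr = x$group$PCr$r_squared,
         k2_per_s = x$group$Pi$k, T1int_Pi_s = x$group$Pi$T1int,
         T1app_Pi_s = x$group$Pi$T1app, r2_Pi = x$group$Pi$r_squared)
  } else if (inherits(x, "functional_report")) {
    agg <- stats::aggregate(cbind(k1, k2, conc_PCr, conc_Pi, pH) ~ label,
                            data = x$blocks, FUN = mean)
    out <- list(n_subjects = length(unique(x$blocks$subject)),
                T1int_PCr_s = x$T1_PCr, T1int_Pi_s = x$T1_Pi,
                atp_conc_mM = x$atp_conc,
                tissue_density_g_mL = x$tissue_density,
                ph_pKa = x$ph_calibration$pKa,
                ph_delta_acid_ppm = x$ph_calibration$delta_acid_ppm,
                ph_delta_base_ppm = x$ph_calibration$delta_base_ppm)
    for (i in seq_len(nrow(agg))) {
      lb <- agg$label[i]
      out[[paste0("k1_", lb)]] <- agg$k1[i]
      out[[paste0("k2_", lb)]] <- agg$k2[i]
      out[[paste0("pH_", lb)]] <- agg$pH[i]
    }
    for (i in seq_len(nrow(x$stats$k1))) {
      cn <- x$stats$k1$contrast[i]
      out[[paste0("k1_pct_change_", cn)]] <- x$stats$k1$mean_pct_change[i]
      out[[paste0("k1_p_", cn)]] <- x$stats$k1$p[i]
    }
    out
  } else stop("no JSON report writer for class ",
              paste(class(x), collapse = "/"), call. = FALSE)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
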