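#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis:
#' synthetic cohort -> preprocessing -> connectivity -> graph measures ->
#' reliability statistics. Defaults describe a compact demonstration
#' cohort (8 subjects x 3 sessions, 32 channels) that exercises every
#' stage in a few minutes; the study-scale layout (214 channels, 44
#' subjects, 12 x 4096-sample epochs, 50 x 5 surrogates, 10000 bootstrap
#' resamples) is reached by overriding the corresponding fields.
#'
#' @param bands Character vector of band names resolved against
#'   [default_bands()], or a named list of [band_spec()] objects.
#' @param measures Connectivity measures: subset of `c("pli", "wpli")`.
#' @param n_subjects,n_sessions Cohort size.
#' @param sigma_between,sigma_within Strength variance components.
#' @param template_strength Population-mean coupling strength.
#' @param common_source_gain Zero-lag common-source amplitude.
#' @param snr Linear SNR of the coupled component.
#' @param background_gain Amplitude of the broadband background component
#'   spanning all configured bands (see [coupling_spec()]).
#' @param coupling_band Name of the band carrying the simulated coupling.
#' @param n_channels,n_regions,n_regional Montage layout.
#' @param n_epochs,n_samples,fs Epoch geometry.
#' @param filter_order Butterworth design order.
#' @param taper Hann taper before the analytic transform.
#' @param n_surrogates,n_iterations Surrogate normalization ensemble.
#' @param icc_form ICC form (see [icc_point()]).
#' @param n_boot Bootstrap resamples for CoV/ICC CIs.
#' @param n_perm Permutations for the topographic test.
#' @param top_fraction Fraction of strongest links to export.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it deterministically.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(bands = c("theta", "alpha1", "alpha2", "beta"),
                            measures = c("pli", "wpli"),
                            n_subjects = 8L, n_sessions = 3L,
                            sigma_between = 0.15, sigma_within = 0.05,
                            template_strength = 0.5,
                            common_source_gain = 0.3, snr = 5,
                            background_gain = 0.5,
                            coupling_band = "beta",
                            n_channels = 32L, n_regions = 6L,
                            n_regional = 24L,
                            n_epochs = 12L, n_samples = 1024L, fs = 256,
                            filter_order = 4L, taper = TRUE,
                            n_surrogates = 20L, n_iterations = 2L,
                            icc_form = "ICC3", n_boot = 1000L,
                            n_perm = 500L, top_fraction = 0.03,
                            seed = 1L) {
  if (is.character(bands)) {
    known <- default_bands()
    bad <- setdiff(bands, names(known))
    if (length(bad) > 0)
      stop("unknown band name(s): ", paste(bad, collapse = ", "),
           " (known: ", paste(names(known), collapse = ", "), ")")
    bands <- known[bands]
  }
  stopifnot(all(vapply(bands, inherits, logical(1), "band_spec")))
  measures <- match.arg(measures, c("pli", "wpli"), several.ok = TRUE)
  if (!coupling_band %in% names(bands))
    stop("coupling_band '", coupling_band, "' is not among the configured bands")
  for (b in bands) check_band_vs_fs(b, fs)
  stopifnot(n_sessions >= 2, icc_form %in% c("ICC3", "ICC2", "ICC1"))
  structure(list(bands = bands, measures = measures,
                 n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 sigma_between = sigma_between, sigma_within = sigma_within,
                 template_strength = template_strength,
                 common_source_gain = common_source_gain, snr = snr,
                 background_gain = background_gain,
                 coupling_band = coupling_band,
                 n_channels = as.integer(n_channels),
                 n_regions = as.integer(n_regions),
                 n_regional = as.integer(n_regional),
                 n_epochs = as.integer(n_epochs),
                 n_samples = as.integer(n_samples), fs = fs,
                 filter_order = as.integer(filter_order), taper = taper,
                 n_surrogates = as.integer(n_surrogates),
                 n_iterations = as.integer(n_iterations),
                 icc_form = icc_form, n_boot = as.integer(n_boot),
                 n_perm = as.integer(n_perm), top_fraction = top_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# every channel joins exactly one coupled pair, so global connectivity
# tracks the cohort's strength gradient rather than the noise floor; a
# broadband background spanning all analysis bands ensures every band
# carries genuine stochastic in-band activity
default_coupling_template <- function(config, montage) {
  nc <- length(montage$labels)
  a <- seq(1L, nc - 1L, by = 2L)
  pairs <- lapply(a, function(ch)
    list(a = ch, b = ch + 1L, lag = pi / 4,
         strength = config$template_strength))
  los <- vapply(config$bands, `[[`, numeric(1), "lo")
  his <- vapply(config$bands, `[[`, numeric(1), "hi")
  coupling_spec(pairs, config$common_source_gain,
                config$bands[[config$coupling_band]], config$snr,
                background = band_spec("background", min(los), max(his)),
                background_gain = config$background_gain)
}

#' Run the simulation stage
#'
#' @param config A [pipeline_config()].
#' @return List with `montage`, `template`, `strengths`, `recordings`.
#' @export
stage_simulate <- function(config) {
  montage <- make_montage(config$n_channels, c(15.3, 19.5, 19.3),
                          config$n_regions, config$n_regional)
  template <- default_coupling_template(config, montage)
  cohort <- cohort_spec(config$n_subjects, config$n_sessions,
                        config$sigma_between, config$sigma_within,
                        seed = derive_seed(config$seed, 1L))
  sim <- simulate_cohort(montage, cohort, template,
                         config$n_epochs, config$n_samples, config$fs)
  c(list(montage = montage, template = template), sim)
}

#' Run preprocessing + connectivity + graph measures for one recording
#'
#' Average reference, band-pass per configured band, analytic signal,
#' PLI/wPLI matrices, global connectivity, graph measures on the
#' epoch-averaged matrix, regional degree, inter-regional links, and the
#' distance correlation.
#'
#' @param rec An `epoched_recording`.
#' @param config A [pipeline_config()].
#' @return List with `rows` (long-format data frame), `nodal` (channel x
#'   band x measure array of nodal degree), `matrices` (subject-average
#'   `conn_matrix` per band/measure).
#' @export
analyze_recording <- function(rec, config) {
  rec <- average_reference(rec)
  subject <- rec$meta$subject %||% NA_integer_
  session <- rec$meta$session %||% NA_integer_
  rows <- list()
  matrices <- list()
  nodal <- array(NA_real_,
                 dim = c(n_channels(rec), length(config$bands),
                         length(config$measures)),
                 dimnames = list(rec$montage$labels, names(config$bands),
                                 config$measures))
  gseed <- derive_seed(config$seed, 1000L + subject, session)
  for (bn in names(config$bands)) {
    band <- config$bands[[bn]]
    ae <- analytic_signal(bandpass(rec, band, config$filter_order), band,
                          config$taper)
    cm <- connectivity_matrices(ae, config$measures)
    for (m in config$measures) {
      avg <- cm[[m]]$average
      matrices[[paste(m, bn, sep = "_")]] <- avg
      gm <- graph_pipeline(avg, config$n_surrogates, config$n_iterations,
                           seed = gseed)
      rd <- regional_degree(avg, rec$montage)
      lk <- inter_regional_links(avg, rec$montage)
      dc <- distance_correlation(avg, rec$montage)
      nodal[, bn, m] <- top_links(avg, config$top_fraction)$nodal_degree
      vals <- c(global = global_connectivity(avg),
                Cw = gm$raw$Cw, Lw = gm$raw$Lw,
                gamma = gm$normalized$gamma, lambda = gm$normalized$lambda,
                swi = gm$normalized$swi, distance_rho = dc$rho,
                stats::setNames(rd, paste0("regdeg_", names(rd))),
                stats::setNames(lk$weight,
                                paste0("link_", lk$region_a, "_",
                                       lk$region_b)))
      rows[[paste(m, bn, sep = "_")]] <-
        data.frame(subject = subject, session = session, band = bn,
                   measure = paste(m, names(vals), sep = "_"),
                   value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  list(rows = do.call(rbind, rows), nodal = nodal, matrices = matrices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline and write a result bundle
#'
#' Stages run in order simulate -> preprocess -> connectivity -> graph ->
#' reliability; all outputs are plain-text TSV/CSV with JSON provenance
#' sidecars (stage, seed, full config echo). Re-running with an identical
#' config reproduces every table bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing and returns the bundle only.
#' @return Invisibly, a list with `cohort_table`, `strengths`, `nodal`
#'   (subjects x bands x channels per measure, baseline), `grand_mean`
#'   matrices, `tables` (the reliability summaries), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- stage_simulate(config)
  tab <- list(); k <- 0L
  nodal <- array(NA_real_,
                 dim = c(config$n_subjects, length(config$bands),
                         config$n_channels, length(config$measures)),
                 dimnames = list(NULL, names(config$bands),
                                 sim$montage$labels, config$measures))
  grand <- list()
  for (i in seq_len(config$n_subjects)) {
    for (s in seq_len(config$n_sessions)) {
      res <- analyze_recording(sim$recordings[[i]][[s]], config)
      k <- k + 1L
      tab[[k]] <- res$rows
      if (s == 1L)
        for (m in config$measures)
          nodal[i, , , m] <- t(res$nodal[, , m])
      if (s == 1L) {
        for (nm in names(res$matrices)) {
          grand[[nm]] <- if (is.null(grand[[nm]])) res$matrices[[nm]]
                         else grand[[nm]] + res$matrices[[nm]]
        }
      }
    }
  }
  cohort_table <- do.call(rbind, tab)
  rownames(cohort_table) <- NULL
  for (nm in names(grand))
    grand[[nm]] <- grand[[nm]] / config$n_subjects
  tables <- stage_reliability(cohort_table, nodal, config)

  bundle <- list(cohort_table = cohort_table, strengths = sim$strengths,
                 nodal = nodal, grand_mean = grand, tables = tables,
                 montage = sim$montage, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

#' Reliability stage over a cohort table
#'
#' CoV (baseline) and ICC with bootstrap CIs for global connectivity and
#' graph measures per band and measure; median (range) ICC over regional
#' degrees and inter-regional links; median distance correlation; RM-ANOVA
#' of global connectivity across bands; topographic max-F permutation test
#' on baseline nodal degree.
#'
#' @param cohort_table Long cohort table (see [analyze_recording()]).
#' @param nodal Baseline nodal-degree array subjects x bands x channels x
#'   measures, or `NULL` to skip the topographic test.
#' @param config A [pipeline_config()].
#' @return Named list of data frames (`cov`, `icc_global`, `icc_regional`,
#'   `icc_links`, `distance_rho`, `band_anova`, `topographic`).
#' @export
stage_reliability <- function(cohort_table, nodal, config) {
  bands <- names(config$bands)
  rseed <- derive_seed(config$seed, 2L)
  scalar_metrics <- c("global", "gamma", "lambda", "swi")
  cov_rows <- list(); iccg_rows <- list()
  iccr_rows <- list(); iccl_rows <- list(); rho_rows <- list()
  for (m in config$measures) {
    for (bn in bands) {
      sub <- cohort_table[cohort_table$band == bn, ]
      for (met in scalar_metrics) {
        mname <- paste(m, met, sep = "_")
        base <- sub$value[sub$measure == mname & sub$session == 1]
        cv <- cov_reliability(base, config$n_boot, rseed)
        cov_rows[[paste(m, bn, met)]] <-
          data.frame(measure = m, band = bn, metric = met,
                     cov = cv$estimate, ci_lo = cv$ci_lo, ci_hi = cv$ci_hi)
        ic <- icc(sub, mname, form = config$icc_form,
                  n_boot = config$n_boot, seed = rseed)
        iccg_rows[[paste(m, bn, met)]] <-
          data.frame(measure = m, band = bn, metric = met,
                     icc = ic$estimate, ci_lo = ic$ci_lo, ci_hi = ic$ci_hi,
                     category = ic$category)
      }
      # regional degrees and links: point ICCs, summarized as median (range)
      reg_names <- unique(grep(paste0("^", m, "_regdeg_"),
                               sub$measure, value = TRUE))
      link_names <- unique(grep(paste0("^", m, "_link_"),
                                sub$measure, value = TRUE))
      reg_icc <- vapply(reg_names, function(nm)
        icc_point(stats::na.omit(cohort_wide(sub, nm)), config$icc_form),
        numeric(1))
      link_icc <- vapply(link_names, function(nm)
        icc_point(stats::na.omit(cohort_wide(sub, nm)), config$icc_form),
        numeric(1))
      iccr_rows[[paste(m, bn)]] <-
        data.frame(measure = m, band = bn, n = length(reg_icc),
                   median_icc = stats::median(reg_icc),
                   min_icc = min(reg_icc), max_icc = max(reg_icc))
      iccl_rows[[paste(m, bn)]] <-
        data.frame(measure = m, band = bn, n = length(link_icc),
                   median_icc = stats::median(link_icc),
                   min_icc = min(link_icc), max_icc = max(link_icc))
      rho <- sub$value[sub$measure == paste0(m, "_distance_rho") &
                         sub$session == 1]
      rho_rows[[paste(m, bn)]] <-
        data.frame(measure = m, band = bn,
                   median_rho = stats::median(rho, na.rm = TRUE))
    }
  }
  anova_rows <- lapply(config$measures, function(m) {
    av <- band_anova(cohort_table, paste0(m, "_global"), session = 1L)
    data.frame(measure = m, F = av$F, df1 = av$df[1], df2 = av$df[2],
               p = av$p)
  })
  topo_rows <- NULL
  if (!is.null(nodal) && length(bands) >= 2) {
    topo_rows <- lapply(config$measures, function(m) {
      pt <- permutation_anova_topographic(nodal[, , , m, drop = TRUE],
                                          config$n_perm, rseed)
      data.frame(measure = m, channel = dimnames(nodal)[[3]],
                 F = pt$F, p_corrected = pt$p_corrected)
    })
    topo_rows <- do.call(rbind, topo_rows)
  }
  list(cov = do.call(rbind, c(cov_rows, list(make.row.names = FALSE))),
       icc_global = do.call(rbind, c(iccg_rows, list(make.row.names = FALSE))),
       icc_regional = do.call(rbind, c(iccr_rows, list(make.row.names = FALSE))),
       icc_links = do.call(rbind, c(iccl_rows, list(make.row.names = FALSE))),
       distance_rho = do.call(rbind, c(rho_rows, list(make.row.names = FALSE))),
       band_anova = do.call(rbind, anova_rows),
       topographic = topo_rows)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  config <- bundle$config
  write_montage(bundle$montage, file.path(out_dir, "montage.csv"))
  utils::write.table(
    data.frame(subject = rep(seq_len(nrow(bundle$strengths)),
                             ncol(bundle$strengths)),
               session = rep(seq_len(ncol(bundle$strengths)),
                             each = nrow(bundle$strengths)),
               strength = as.vector(bundle$strengths)),
    file.path(out_dir, "cohort_strengths.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  write_cohort_table(bundle$cohort_table,
                     file.path(out_dir, "cohort_table.tsv"))
  for (nm in names(bundle$grand_mean)) {
    write_conn_matrix(bundle$grand_mean[[nm]],
                      file.path(out_dir, paste0("grand_mean_", nm, ".tsv")))
    tl <- top_links(bundle$grand_mean[[nm]], config$top_fraction)
    utils::write.table(tl$edges,
                       file.path(out_dir, paste0("top_links_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(bundle$tables))
    if (!is.null(bundle$tables[[nm]]))
      utils::write.table(bundle$tables[[nm]],
                         file.path(out_dir, "tables", paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(file.path(out_dir, "provenance.json"),
                config = unclass(config), seed = config$seed,
                stage = "run_pipeline")
  invisible(out_dir)
}

#' Summarize a result bundle directory
#'
#' Reads the reliability tables written by [run_pipeline()] and returns
#' them as a named list, printing a compact summary. Missing stage outputs
#' are listed rather than failing.
#'
#' @param results_dir Bundle directory.
#' @param quiet Suppress printing.
#' @return Named list of data frames; attribute `missing` lists absent
#'   tables.
#' @export
report_bundle <- function(results_dir, quiet = FALSE) {
  expected <- c("cov", "icc_global", "icc_regional", "icc_links",
                "distance_rho", "band_anova", "topographic")
  out <- list(); missing <- character()
  for (nm in expected) {
    path <- file.path(results_dir, "tables", paste0(nm, ".tsv"))
    if (file.exists(path)) out[[nm]] <- utils::read.delim(path)
    else missing <- c(missing, nm)
  }
  if (!quiet) {
    if (length(out) == 0) {
      cat("empty report:", results_dir, "contains no reliability tables\n")
    } else {
      for (nm in names(out))
        cat(sprintf("%-13s %3d rows\n", nm, nrow(out[[nm]])))
    }
    if (length(missing) > 0)
      cat("missing tables:", paste(missing, collapse = ", "), "\n")
  }
  attr(out, "missing") <- missing
  invisible(out)
}
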