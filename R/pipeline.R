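#' Assemble a run configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the defaults. Keys:
#' `sequence` (one-letter string) or `fasta` (path); `shift_table` (optional
#' TSV overriding the generator); `seed`; `experiment` (one of the 5D names,
#' `"HNCO_3D"`, or `"complementary_4d"` for the pair of 1+3 4D experiments);
#' `field_mhz`; `dispersion_scale`; `mixing` (`J_hz`, `t_mix_ms`,
#' `R600_per_s`); `axes` (`n_anchor`, `n_resolved`); `n_points`; `snr` (peak
#' signal-to-noise of the weakest emitted peak in the sections; `0` =
#' noiseless); `pick` (`threshold`, `min_separation` in Nyquist grid steps,
#' `oversample`, `n_off`, `apodize`, `rel_floor`); `tol` (`CO`, `N` in ppm);
#' `amplitude_floor`; `exchange_attenuation` (named list residue index ->
#' factor); `outdir` (artifacts written there if set); `write_fid`.
#'
#' @param x Path to a YAML config, or a named list.
#' @return A validated config list of class `conconnmr_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("config file %s does not exist.", x))
    x <- yaml::read_yaml(x)
  }
  defaults <- list(
    sequence = NULL, fasta = NULL, shift_table = NULL,
    seed = 1, experiment = "HACACONCOCONH_5D", field_mhz = 600,
    dispersion_scale = 1,
    mixing = list(J_hz = 1.0, t_mix_ms = 250, R600_per_s = 1.43),
    axes = list(n_anchor = 64, n_resolved = 64),
    n_points = 1100, snr = 20,
    pick = list(threshold = 5, min_separation = 2, oversample = 2, n_off = 50,
                apodize = "cosine", rel_floor = 0.1),
    tol = list(CO = 0.05, N = 0.2),
    amplitude_floor = 0.01, exchange_attenuation = NULL,
    outdir = NULL, write_fid = FALSE
  )
  cfg <- utils::modifyList(defaults, x)
  valid_exp <- c("HNCO_3D", "HNCOCONH_5D", "HACACONCOCONH_5D", "complementary_4d")
  if (!cfg$experiment %in% valid_exp) {
    abort(sprintf("unsupported experiment '%s' (one of: %s).",
                  cfg$experiment, paste(valid_exp, collapse = ", ")))
  }
  if (is.null(cfg$sequence) && is.null(cfg$fasta) && is.null(cfg$shift_table)) {
    abort("config must provide `sequence`, `fasta` or `shift_table`.")
  }
  for (f in c("fasta", "shift_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(sprintf("config key `%s`: file %s does not exist.", f, cfg[[f]]))
    }
  }
  structure(cfg, class = c("conconnmr_config", "list"))
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full simulation and assignment pipeline
#'
#' Executes, in order: ground-truth shift generation (or loading), peak
#' enumeration, NUS schedule generation, time-domain synthesis, sparse-FT
#' cross-section reconstruction and peak picking per anchor strip, link-graph
#' construction, chain assembly, and scoring against the ground truth. The
#' run is deterministic for a given config (all randomness derives from
#' `config$seed`); stage failures abort with the stage name. Counts per stage
#' are logged via `message()`.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @return An object of class `conconnmr_run`: list with `config`, `shifts`,
#'   `peaks`, `schedule`, `anchors`, `strips`, `links`, `chains`, `stats`,
#'   `map` and `timings`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "conconnmr_config")) config <- run_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  shifts <- stage("shifts", {
    if (!is.null(config$shift_table)) {
      read_shift_table(config$shift_table)
    } else {
      seqstr <- config$sequence %||% read_fasta_sequence(config$fasta)
      generate_shifts(seqstr, seed = config$seed,
                      dispersion_scale = config$dispersion_scale)
    }
  })
  message(sprintf("[shifts] %d residues, %d prolines",
                  nrow(shifts), sum(shifts$is_proline)))
  tick("shifts")

  model <- mixing_model(config$mixing$J_hz, config$mixing$t_mix_ms,
                        config$mixing$R600_per_s, config$field_mhz)
  ex <- NULL
  if (!is.null(config$exchange_attenuation)) {
    ex <- rep(1, nrow(shifts))
    idx <- as.integer(names(config$exchange_attenuation))
    ex[idx] <- unlist(config$exchange_attenuation)
  }

  exp_names <- switch(config$experiment,
    complementary_4d = c("HACACO_NCO_CONH_4D_CO", "HACACO_N_CO_CONH_4D_N"),
    config$experiment)

  anchors <- stage("anchors", {
    k <- anchor_residues(shifts$aa)
    tibble(id = sprintf("%s%d", shifts$aa[k], k), residue = k,
           CO = shifts$CO[k - 1L], N = shifts$N[k])
  })

  per_exp <- purrr::map(exp_names, function(expn) {
    experiment <- experiment_spec(expn)
    peaks <- stage("peaks", enumerate_peaks(
      shifts, experiment, model, exchange_attenuation = ex,
      amplitude_floor = config$amplitude_floor))
    message(sprintf("[peaks:%s] %d peaks emitted", expn, nrow(peaks)))
    if (expn == "HNCO_3D") return(list(experiment = experiment, peaks = peaks))

    axes <- default_axes(experiment, config$field_mhz,
                         n_anchor = config$axes$n_anchor,
                         n_resolved = config$axes$n_resolved)
    grid <- prod(axes$n[axes$nus])
    n_pts <- config$n_points
    if (config$experiment == "complementary_4d" && n_pts > grid) {
      message(sprintf("[schedule:%s] clamping n_points to the %d-point resolved grid",
                      expn, grid))
      n_pts <- grid
    }
    schedule <- stage("schedule", make_schedule(axes, n_pts, seed = config$seed))
    message(sprintf("[schedule:%s] %d of %d grid points sampled",
                    expn, nrow(schedule), grid))

    noise_sigma <- 0
    if (!is.null(config$snr) && config$snr > 0) {
      h_min <- predicted_min_height(peaks, axes, schedule)
      m_total <- prod(axes$n[!axes$nus]) * nrow(schedule)
      noise_sigma <- h_min * sqrt(m_total) / config$snr
    }
    fid <- stage("synthesize", synthesize_fid(
      peaks, axes, schedule, noise_sigma = noise_sigma,
      seed = child_seed(config$seed, 7)))
    message(sprintf("[synthesize:%s] %d stored complex points, noise sigma %.3g",
                    expn, length(fid$values), noise_sigma))

    resolved <- experiment$resolved
    picks <- purrr::map_dfr(seq_len(nrow(anchors)), function(r) {
      anc <- c(N = anchors$N[r], CO = anchors$CO[r])
      own <- peaks[peaks$anchor == anchors$residue[r], , drop = FALSE]
      sec <- cross_section(fid, anc, resolved,
                           oversample = config$pick$oversample,
                           apodize = config$pick$apodize,
                           label = anchors$id[r])
      nl <- sampling_noise_level(fid, anc, resolved, peaks = own,
                                 n_off = config$pick$n_off,
                                 seed = child_seed(config$seed, 900 + r),
                                 apodize = config$pick$apodize)
      pk <- pick_peaks(sec, nl, threshold = config$pick$threshold,
                       min_separation = config$pick$min_separation,
                       rel_floor = config$pick$rel_floor)
      if (nrow(pk) == 0) return(NULL)
      pk$anchor_id <- anchors$id[r]
      pk
    })
    message(sprintf("[pick:%s] %d sections computed, %d picks",
                    expn, nrow(anchors), nrow(picks)))
    list(experiment = experiment, peaks = peaks, axes = axes,
         schedule = schedule, fid = if (isTRUE(config$write_fid)) fid else NULL,
         picks = picks)
  })
  names(per_exp) <- exp_names
  tick("reconstruction")

  score_exp <- experiment_spec(
    if (config$experiment == "complementary_4d") "HACACONCOCONH_5D" else config$experiment)
  links <- chains <- stats <- map <- NULL
  if (config$experiment %in% c("HNCOCONH_5D", "HACACONCOCONH_5D")) {
    picks <- per_exp[[1]]$picks
    strips <- tibble(anchor_id = picks$anchor_id, CO = picks$COres,
                     N = picks$Nres, height = picks$height)
  } else if (config$experiment == "complementary_4d") {
    pc <- per_exp[["HACACO_NCO_CONH_4D_CO"]]$picks
    pn <- per_exp[["HACACO_N_CO_CONH_4D_N"]]$picks
    strips <- combine_4d_picks(
      tibble(anchor_id = pc$anchor_id, CO = pc$COres, height = pc$height),
      tibble(anchor_id = pn$anchor_id, N = pn$Nres, height = pn$height))
  } else {
    strips <- NULL
  }
  if (!is.null(strips)) {
    links <- stage("link", build_links(strips, anchors,
                                       tol_co = config$tol$CO, tol_n = config$tol$N))
    chains <- stage("assemble", assemble_chains(links))
    stats <- stage("evaluate", score_links(links, shifts, score_exp))
    map <- assignment_map(links, shifts, score_exp)
    g <- glance(links)
    message(sprintf("[link] %d edges, %d bridges, %d ambiguous, %d unmatched; %d chains",
                    g$n_edges, g$n_bridges, g$n_ambiguous, g$n_unmatched,
                    max(chains$chain)))
    message(sprintf("[evaluate] forward %s | backward %s",
                    stats$label[1], stats$label[2]))
  }
  tick("assignment")

  run <- structure(list(
    config = config, shifts = shifts, anchors = anchors, results = per_exp,
    strips = strips, links = links, chains = chains, stats = stats, map = map,
    timings = timings
  ), class = "conconnmr_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

# expected section height of the weakest emitted peak: amplitude times the
# mean decay over the sampled grid; calibrates the noise draw so that the
# requested SNR holds for every true peak
predicted_min_height <- function(peaks, axes, schedule) {
  decay <- rep(1, nrow(peaks))
  for (d in seq_len(nrow(axes))) {
    ax <- axes[d, ]
    t <- if (ax$nus) schedule[[ax$label]] / ax$sw_hz else (seq_len(ax$n) - 1) / ax$sw_hz
    decay <- decay * mean(exp(-ax$r2 * t))
  }
  min(peaks$amplitude * decay)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  class(cfg) <- "list"
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  write_shift_table(run$shifts, file.path(outdir, "shifts.tsv"))
  readr::write_tsv(run$anchors, file.path(outdir, "anchors.tsv"))
  for (expn in names(run$results)) {
    res <- run$results[[expn]]
    write_peaks_tsv(res$peaks, file.path(outdir, paste0("peaks_", expn, ".tsv")))
    write_sparky(res$peaks, file.path(outdir, paste0("peaks_", expn, ".list")),
                 shifts = run$shifts)
    if (!is.null(res$schedule)) {
      write_schedule(res$schedule, file.path(outdir, paste0("schedule_", expn, ".txt")))
    }
    if (!is.null(res$picks) && nrow(res$picks)) {
      readr::write_tsv(res$picks, file.path(outdir, paste0("picks_", expn, ".tsv")))
    }
    if (!is.null(res$fid)) {
      write_fid_tsv(res$fid, file.path(outdir, paste0("fid_", expn, ".tsv")))
    }
  }
  if (!is.null(run$links)) {
    readr::write_tsv(tidy(run$links), file.path(outdir, "links.tsv"))
    readr::write_tsv(run$chains, file.path(outdir, "chains.tsv"))
    readr::write_tsv(run$map, file.path(outdir, "assignment_map.tsv"))
    writeLines(c(sprintf("Forward links\t%s", run$stats$label[1]),
                 sprintf("Backwards links\t%s", run$stats$label[2])),
               file.path(outdir, "link_stats.txt"))
  }
  invisible(outdir)
}

#' @export
print.conconnmr_run <- function(x, ...) {
  cat("<conconnmr run>", x$config$experiment, "\n")
  cat("  residues:", nrow(x$shifts), "| anchors:", nrow(x$anchors), "\n")
  if (!is.null(x$stats)) {
    cat(sprintf("  forward %s | backward %s\n", x$stats$label[1], x$stats$label[2]))
  }
  invisible(x)
}

#' @method tidy conconnmr_run
#' @export
tidy.conconnmr_run <- function(x, ...) {
  if (is.null(x$stats)) return(tibble())
  as_tibble(x$stats)
}

#' @method glance conconnmr_run
#' @export
glance.conconnmr_run <- function(x, ...) {
  g <- if (is.null(x$links)) tibble() else glance(x$links)
  dplyr::bind_cols(
    tibble(experiment = x$config$experiment, n_residues = nrow(x$shifts),
           n_strips = nrow(x$anchors)), g)
}
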