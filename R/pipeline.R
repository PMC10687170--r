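# End-to-end orchestration: simulate -> fit behavior -> preprocess ->
# cluster statistic -> encoding / connectivity, with a machine-readable
# report. Every stage is an exported function; this module wires them
# together under one configuration object whose defaults reproduce the
# study's analysis constants.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis constants of the study design: 60 Hz
#' notch with 3 Hz bandwidth at the -1 dB point, Morlet omega0 = 6 on a
#' log 1-200 Hz axis, 100 ms windows every 50 ms, permutation N = 1000 at
#' alpha = 0.05, FDR q = 0.015, cluster minima of 250 ms and one octave,
#' decay-constant grid step 0.01, SE tolerance 0.13, and 20\% perturbation
#' probability. Any field can be overridden; reduced sizes (sample rate,
#' permutations, epochs) are intended for desk-scale runs.
#'
#' @param n_subjects cohort size.
#' @param generator named list of \code{\link{generator_spec}} overrides.
#' @param performance_gradient passed to \code{\link{simulate_cohort}}.
#' @param channels channel table (channel_id, region, network) shared by
#'   all subjects.
#' @param lfp named list: sample_rate, epoch_layout, encoding_targets,
#'   one_over_f_exponent, line_amp, subject_gain_mult (per-subject
#'   multiplier on every target gain).
#' @param spectral named list: bins_per_octave, fmin, fmax, window, step,
#'   omega0, notch.
#' @param cluster named list: n_perm, alpha, q, min_time, min_octaves,
#'   threshold.
#' @param selection named list: r_thresh, p_thresh, truncation,
#'   min_subjects.
#' @param state which internal state drives the neural analysis
#'   ("error" or "perturbed").
#' @param grid_step,criterion behavioral fitting controls.
#' @param seed master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subjects = 4,
                            generator = list(),
                            performance_gradient = 1,
                            channels = NULL,
                            lfp = list(),
                            spectral = list(),
                            cluster = list(),
                            selection = list(),
                            state = c("error", "perturbed"),
                            grid_step = 0.01,
                            criterion = "rmse",
                            seed = 1L) {
  state <- match.arg(state)
  # shallow merge: supplied fields replace defaults wholesale (modifyList
  # would recurse into unnamed lists like encoding_targets and drop them)
  merge_over <- function(defaults, supplied) {
    for (nm in names(supplied)) defaults[[nm]] <- supplied[[nm]]
    defaults
  }
  lfp <- merge_over(list(
    sample_rate = 2000,
    epoch_layout = stats::setNames(rep(0.6, 8), TASK_EPOCHS),
    encoding_targets = list(),
    one_over_f_exponent = 1, line_amp = 1,
    subject_gain_mult = rep(1, n_subjects)), lfp)
  spectral <- merge_over(list(
    bins_per_octave = 12, fmin = 1, fmax = 200,
    window = 0.1, step = 0.05, omega0 = 6, notch = TRUE), spectral)
  cluster <- merge_over(list(
    n_perm = 1000, alpha = 0.05, q = 0.015,
    min_time = 0.25, min_octaves = 1, threshold = "subject_t"), cluster)
  selection <- merge_over(list(
    r_thresh = 0.75, p_thresh = 0.05, truncation = 0.5,
    min_subjects = 3), selection)
  structure(list(n_subjects = n_subjects, generator = generator,
                 performance_gradient = performance_gradient,
                 channels = channels, lfp = lfp, spectral = spectral,
                 cluster = cluster, selection = selection, state = state,
                 grid_step = grid_step, criterion = criterion,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON round trip)
#' @param config a \code{pipeline_config}.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  # named vectors serialize as bare arrays; keep names via lists
  out$lfp$epoch_layout <- as.list(out$lfp$epoch_layout)
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lfp <- raw$lfp
  lfp$epoch_layout <- unlist(lfp$epoch_layout)
  lfp$subject_gain_mult <- unlist(lfp$subject_gain_mult)
  lfp$encoding_targets <- lapply(lfp$encoding_targets, function(tg) {
    for (nm in c("time_window", "freq_band", "epochs")) {
      if (!is.null(tg[[nm]])) tg[[nm]] <- unlist(tg[[nm]])
    }
    tg
  })
  channels <- if (length(raw$channels)) {
    do.call(rbind, lapply(raw$channels, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  } else NULL
  pipeline_config(n_subjects = raw$n_subjects,
                  generator = lapply(raw$generator, function(x)
                    if (is.list(x)) unlist(x) else x),
                  performance_gradient = raw$performance_gradient,
                  channels = channels,
                  lfp = lfp,
                  spectral = lapply(raw$spectral, unlist),
                  cluster = lapply(raw$cluster, unlist),
                  selection = lapply(raw$selection, unlist),
                  state = raw$state, grid_step = raw$grid_step,
                  criterion = raw$criterion, seed = raw$seed)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, fits each subject's internal-state model by grid
#' search, synthesizes and preprocesses the LFP, runs the hierarchical
#' cluster-permutation statistic per region and epoch, applies the size
#' filter and FDR correction, groups surviving clusters, and computes
#' encoding strengths with performance selection plus subject /
#' population / performance connectivity for region pairs.
#'
#' @param config a \code{pipeline_config} with a non-NULL channel table.
#' @return list of class \code{pipeline_report} with elements
#'   \code{behavior} (per-subject decay constants, weights, metrics),
#'   \code{performance}, \code{clusters} (per-cluster table),
#'   \code{groups}, \code{encoding}, \code{connectivity}, and
#'   \code{provenance} (config and seed).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$channels)) stop("config$channels must be provided")
  seeds <- derive_seeds(config$seed, 3 + config$n_subjects)

  ## 1. behavior: simulate and fit
  gen <- do.call(generator_spec, config$generator)
  cohort <- simulate_cohort(config$n_subjects, gen,
                            performance_gradient =
                              config$performance_gradient,
                            seed = seeds[1])
  fits <- lapply(cohort$sessions, grid_search_fit,
                 grid_step = config$grid_step,
                 criterion = config$criterion)
  perf <- cohort$performance

  ## 2. neural: synthesize + preprocess per subject
  state_of <- function(fit) {
    if (config$state == "error") fit$states$x_se_z else fit$states$x_p_z
  }
  subjects <- names(cohort$sessions)
  spects <- list()   # [[subject]][[channel]] -> list of epochs
  for (i in seq_along(subjects)) {
    trials <- cohort$sessions[[i]]
    fit <- fits[[i]]
    lspec <- lfp_spec(
      channels = config$channels,
      sample_rate = config$lfp$sample_rate,
      epoch_layout = config$lfp$epoch_layout,
      encoding_targets = lapply(config$lfp$encoding_targets, function(tg) {
        tg$gain <- tg$gain * config$lfp$subject_gain_mult[i]
        tg
      }),
      one_over_f_exponent = config$lfp$one_over_f_exponent,
      line_amp = config$lfp$line_amp)
    rec <- synthesize_lfp(trials,
                          states = list(error = fit$states$x_se_z,
                                        perturbed = fit$states$x_p_z),
                          spec = lspec, seed = seeds[3 + i])
    freqs <- cwt_freqs(config$spectral$fmin, config$spectral$fmax,
                       config$spectral$bins_per_octave)
    freqs <- freqs[freqs < config$lfp$sample_rate / 2 / 1.05]
    spects[[subjects[i]]] <- lapply(
      config$channels$channel_id, function(ch)
        preprocess_channel(rec, ch, freqs = freqs,
                           trials_keep = which(trials$completed),
                           window = config$spectral$window,
                           step = config$spectral$step,
                           notch = config$spectral$notch,
                           omega0 = config$spectral$omega0))
    names(spects[[subjects[i]]]) <- config$channels$channel_id
  }
  freqs <- spects[[1]][[1]][[1]]$freqs

  ## 3. cluster statistic per region x epoch
  regions <- unique(config$channels$region)
  epochs <- names(config$lfp$epoch_layout)
  cl_rows <- NULL
  cl_masks <- list()
  perm_seeds <- derive_seeds(seeds[2], length(regions) * length(epochs))
  k <- 0
  for (rg in regions) {
    chans <- config$channels$channel_id[config$channels$region == rg]
    for (ep in epochs) {
      k <- k + 1
      sb <- lapply(subjects, function(s)
        lapply(chans, function(ch) spects[[s]][[ch]][[ep]]))
      st <- lapply(seq_along(subjects), function(i) state_of(fits[[i]]))
      res <- permutation_test(sb, st, n_perm = config$cluster$n_perm,
                              alpha = config$cluster$alpha,
                              seed = perm_seeds[k],
                              threshold = config$cluster$threshold)
      for (cl in res$clusters) {
        if (!filter_cluster_size(cl, freqs, step = config$spectral$step,
                                 min_time = config$cluster$min_time,
                                 min_octaves = config$cluster$min_octaves))
          next
        cl_masks[[length(cl_masks) + 1]] <- cl$mask
        cl_rows <- rbind(cl_rows, data.frame(
          region = rg, epoch = ep, mass = cl$mass,
          p_signed = cl$p_signed,
          t0 = (cl$time_idx[1] - 1) * config$spectral$step,
          t1 = cl$time_idx[2] * config$spectral$step,
          f_lo = freqs[cl$freq_idx[1]], f_hi = freqs[cl$freq_idx[2]],
          mask_id = length(cl_masks), stringsAsFactors = FALSE))
      }
    }
  }

  ## 4. FDR + grouping
  groups <- encoding <- connectivity <- NULL
  if (!is.null(cl_rows)) {
    keep <- fdr_correct(cl_rows$p_signed, q = config$cluster$q)
    surv <- cl_rows[keep, , drop = FALSE]
    if (nrow(surv) > 0) {
      surv$freq_bins <- lapply(surv$mask_id, function(id) {
        m <- cl_masks[[id]]
        ((which(m) - 1) %/% nrow(m)) + 1
      })
      groups <- group_and_label(surv, freqs, all_epochs = epochs)

      ## 5. encoding + connectivity per group
      group_series <- list()  # [[group]][[subject]][[channel]]
      for (gi in seq_len(nrow(groups))) {
        g <- groups$group_id[gi]
        members <- surv[groups$members[[gi]], , drop = FALSE]
        g_masks <- lapply(members$mask_id, function(id) cl_masks[[id]])
        chans <- config$channels$channel_id[
          config$channels$region == groups$region[gi]]
        series <- lapply(subjects, function(s)
          lapply(chans, function(ch)
            trial_power_series(
              lapply(members$epoch,
                     function(ep) spects[[s]][[ch]][[ep]]),
              g_masks)))
        names(series) <- subjects
        group_series[[gi]] <- series
        strengths <- vapply(subjects, function(s)
          encoding_strength(series[[s]],
                            state_of(fits[[which(subjects == s)]])),
          numeric(1))
        sel <- if (length(subjects) >= config$selection$min_subjects)
          select_performance_regions(strengths, perf,
                                     r_thresh = config$selection$r_thresh,
                                     p_thresh = config$selection$p_thresh)
        else list(performance_r = NA, performance_p = NA, selected = FALSE)
        encoding <- rbind(encoding, data.frame(
          region = groups$region[gi], group_id = g,
          band = groups$band[gi],
          mean_strength = mean(strengths),
          performance_r = sel$performance_r,
          performance_p = sel$performance_p,
          selected = isTRUE(sel$selected), stringsAsFactors = FALSE))
      }
      if (nrow(groups) >= 2) {
        for (a in seq_len(nrow(groups) - 1)) for (b in (a + 1):nrow(groups)) {
          subj_str <- vapply(subjects, function(s) {
            m <- channel_connectivity(group_series[[a]][[s]],
                                      group_series[[b]][[s]])
            subject_connectivity(
              m, same_region = groups$region[a] == groups$region[b])
          }, numeric(1))
          pc <- performance_connectivity(
            subj_str, perf, min_subjects = config$selection$min_subjects,
            truncation = config$selection$truncation)
          connectivity <- rbind(connectivity, data.frame(
            region_a = groups$region[a], region_b = groups$region[b],
            group_a = groups$group_id[a], group_b = groups$group_id[b],
            population_strength = if (length(subj_str) >= 2)
              population_connectivity(subj_str) else NA_real_,
            performance_strength = pc$performance_r,
            exported = isTRUE(pc$exported), stringsAsFactors = FALSE))
        }
      }
    }
  }

  behavior <- lapply(seq_along(subjects), function(i) {
    f <- fits[[i]]
    list(subject_id = subjects[i], alpha_se = f$params$alpha_se,
         alpha_p = f$params$alpha_p,
         rt_weights = as.list(f$rt_weights),
         se_weights = as.list(f$se_weights),
         metrics = f$metrics, performance = unname(perf[i]))
  })
  structure(list(behavior = behavior, performance = perf,
                 clusters = cl_rows, groups = groups,
                 encoding = encoding, connectivity = connectivity,
                 provenance = list(config = unclass(config),
                                   seed = config$seed)),
            class = "pipeline_report")
}

#' Write a pipeline report to JSON (tables also as CSV alongside)
#'
#' @param report a \code{pipeline_report}.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- report$clusters
  if (!is.null(cl)) cl$freq_bins <- NULL
  gr <- report$groups
  if (!is.null(gr)) gr$members <- NULL
  jsonlite::write_json(
    list(behavior = report$behavior,
         performance = as.list(report$performance),
         clusters = cl, groups = gr,
         encoding = report$encoding, connectivity = report$connectivity,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  for (nm in c("clusters", "groups", "encoding", "connectivity")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    tab$freq_bins <- NULL
    tab$members <- NULL
    utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
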