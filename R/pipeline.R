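.default_config <- function() {
  list(
    wavelet = list(name = "db4", levels = 9L, rule = "improved",
                   lambda_method = "universal", lambdas = NULL,
                   improved_variant = "adopted"),
    ica = list(n_components = NULL, tol = 1e-6, max_iter = 200L,
               grad_refine_steps = 5L, mode = "refine_fixed_point",
               var_floor = 1e-9),
    fuzzyen = list(m = 2L, r_factor = 0.2, window = 5000L),
    classify = list(boundary_mode = "exclusive"),
    simulate = list(duration = 60, fs = 1000, contamination_db = 0,
                    noise_sd = 0.3, heart_rate = 72, passband = c(20, 250)),
    seed = NULL
  )
}

check_config_keys <- function(user, defaults, path = character()) {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop_input("unknown config key(s): ",
               paste(paste(c(path, ""), collapse = "."), extra,
                     sep = "", collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_config_keys(as.list(user[[nm]]), defaults[[nm]], c(path, nm))
    }
  }
}

#' Pipeline configuration
#'
#' Builds the full configuration for [remove_ecg()] and the command-line
#' interface by merging user overrides into the documented defaults. Unknown
#' keys are rejected. Groups: `wavelet` (`name`, `levels` — integer or
#' `"auto"` —, `rule`, `lambda_method`, `lambdas`, `improved_variant`),
#' `ica` (`n_components`, `tol`, `max_iter`, `grad_refine_steps`, `mode`,
#' `var_floor`), `fuzzyen` (`m`, `r_factor`, `window`), `classify`
#' (`boundary_mode`), `simulate` (`duration`, `fs`, `contamination_db`,
#' `noise_sd`, `heart_rate`, `passband`), and `seed`.
#'
#' @param ... Named overrides, e.g. `wavelet = list(rule = "soft")`,
#'   `seed = 7`.
#' @return A `pipeline_config` list with all defaults filled in.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- .default_config()
  check_config_keys(user, defaults)
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Remove ECG artifacts from a multichannel sEMG record
#'
#' The full artifact-removal chain: per-channel multi-level wavelet
#' denoising ([wavelet_denoise()]), channel centering and PCA whitening
#' ([pca_whiten()]), deflationary negentropy FastICA
#' ([extract_components()]), fuzzy-entropy scoring of every separated
#' component ([fuzzy_entropy()], computed on a centered unit-variance copy
#' over a centered window), entropy-gap ECG identification
#' ([classify_components()]), and reconstruction with the flagged
#' components eliminated ([reconstruct_channels()]). The eliminated part is
#' returned as the ECG artifact estimate, so `clean + artifact` equals the
#' denoised record.
#'
#' @param record An `mc_record` with at least 3 channels.
#' @param config A [pipeline_config()] (default configuration if omitted).
#' @return List with `clean` (`mc_record`), `artifact` (`mc_record`,
#'   `denoised - clean`), `unmixing` (the fitted `unmixing_model`, whose
#'   `sources` rows are the separated components), `whitening` (the
#'   `whitening_model`), and `report` (classification, per-component
#'   entropies and iteration counts, resolved configuration, per-stage
#'   timings).
#' @export
remove_ecg <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "mc_record"), inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop_input("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  wv <- config$wavelet
  denoised <- tick("wavelet_denoise",
                   wavelet_denoise(record, wv$name, wv$levels, wv$rule,
                                   wv$lambda_method, wv$lambdas,
                                   wv$improved_variant))
  cen <- tick("center", center_channels(denoised$samples))
  wh <- tick("pca_whiten",
             pca_whiten(cen$X, config$ica$var_floor, mean = cen$mean))
  if (wh$model$kept_dims < 3L) {
    stop_input("pipeline failed at stage 'pca_whiten': only ",
               wh$model$kept_dims,
               " usable whitened dimension(s); the entropy-gap rule needs >= 3")
  }
  nc <- config$ica$n_components %||% wh$model$kept_dims
  um <- tick("fastica",
             extract_components(wh$Z, nc, config$ica$tol, config$ica$max_iter,
                                config$ica$grad_refine_steps, config$ica$mode,
                                seed = config$seed, whitening = wh$model))
  if (!any(um$converged)) {
    stop_input("pipeline failed at stage 'fastica': no component converged")
  }
  ents <- tick("fuzzy_entropy", vapply(seq_len(nrow(um$sources)), function(i) {
    y <- um$sources[i, ]
    y <- (y - mean(y)) / stats::sd(y)
    fuzzy_entropy(y, config$fuzzyen$m, config$fuzzyen$r_factor,
                  window = config$fuzzyen$window)
  }, numeric(1)))
  cls <- tick("classify",
              classify_components(ents, config$classify$boundary_mode))
  if (any(cls$ecg_flags)) {
    clean_mat <- tick("reconstruct",
                      reconstruct_channels(um, !cls$ecg_flags, wh$model))
    clean <- new_record(clean_mat, record$fs, record$labels,
                        provenance = c(denoised$provenance,
                                       sprintf("remove_ecg(dropped=%s)",
                                               paste(which(cls$ecg_flags),
                                                     collapse = ","))))
  } else {
    clean <- denoised
    clean$provenance <- c(denoised$provenance, "remove_ecg(dropped=none)")
  }
  artifact <- new_record(denoised$samples - clean$samples, record$fs,
                         record$labels,
                         provenance = c(denoised$provenance,
                                        "remove_ecg(artifact estimate)"))
  list(clean = clean, artifact = artifact, unmixing = um,
       whitening = wh$model,
       report = list(classification = cls, entropies = ents,
                     n_iter = um$n_iter, converged = um$converged,
                     kept_dims = wh$model$kept_dims,
                     config = unclass(config), timings = timings))
}

# serialize a pipeline report as a flat key-value text document
report_to_text <- function(report) {
  cls <- report$classification
  c(sprintf("entropies: %s", paste(sprintf("%.17g", cls$entropies), collapse = " ")),
    sprintf("order: %s", paste(cls$order, collapse = " ")),
    sprintf("k: %s", ifelse(is.na(cls$k), "none", cls$k)),
    sprintf("boundary_mode: %s", cls$boundary_mode),
    sprintf("ecg_components: %s",
            if (any(cls$ecg_flags)) paste(which(cls$ecg_flags), collapse = " ")
            else "none"),
    sprintf("n_iter: %s", paste(report$n_iter, collapse = " ")),
    sprintf("converged: %s", paste(report$converged, collapse = " ")),
    sprintf("kept_dims: %d", report$kept_dims),
    sprintf("config: %s", gsub("\n", " ", yaml::as.yaml(report$config))))
}
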