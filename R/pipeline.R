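#' Spike-locked cortical source coherence analysis
#'
#' Runs the full analysis chain on in-memory objects: spike-centred
#' segmentation, regularized inverse source estimation, carving into the
#' pre-spike / spike / post-spike 1-s intervals, parcel averaging, coherence
#' matrices per frequency bin and band, and top-K edge extraction.
#'
#' @param rec a [sensor_recording()] with spike times.
#' @param K lead field, sensors x patches.
#' @param W smoothing operator from [build_laplacian()], or `NULL` for
#'   minimum norm.
#' @param parcel_map parcel table (see [average_by_parcel()]).
#' @param method `"csl"` (requires `W`) or `"minimum_norm"`.
#' @param alpha regularization weight or `"gcv"` (default).
#' @param pre_s,post_s segmentation window around each spike peak (s).
#' @param interval_s analysis interval length (s, default 1).
#' @param fmin,fmax coherence frequency range (Hz).
#' @param k number of top edges per band (default 100).
#' @param per_band top-k within each band (default) or pooled.
#' @return An object of class `spike_coherence`: list with `coherence`
#'   (a [coherence_matrix()] result over the three intervals), `edges`
#'   (data.frame of top-k edges per interval and band), `inverse` (the
#'   [solve_inverse()] fit on the concatenated spike segments), `n_spikes`,
#'   `parcels`, `settings`.
#' @export
spike_coherence <- function(rec, K, W = NULL, parcel_map,
                            method = c("csl", "minimum_norm"),
                            alpha = "gcv", pre_s = 1.5, post_s = 1.5,
                            interval_s = 1, fmin = 1, fmax = 70, k = 100,
                            per_band = TRUE) {
  method <- match.arg(method)
  if (method == "minimum_norm") W <- NULL
  if (method == "csl" && is.null(W)) {
    stop("method 'csl' requires a Laplacian operator W")
  }
  pm <- normalize_parcel_map(parcel_map)
  if (nrow(pm) != ncol(K)) {
    stop("parcel map covers ", nrow(pm), " patches but the lead field has ",
         ncol(K), " columns")
  }

  segs <- segment_spikes(rec, pre_s = pre_s, post_s = post_s)
  dm <- dim(segs)
  n_spikes <- dm[3L]

  # one linear solve over all spike segments (the operator is sample-wise)
  flat <- matrix(segs, dm[1L], dm[2L] * dm[3L])
  fit <- solve_inverse(K, flat, W = W, alpha = alpha)
  J <- array(as.matrix(coef(fit)), dim = c(ncol(K), dm[2L], n_spikes))
  attr(J, "fs") <- rec$fs

  ivs <- carve_intervals(J, fs = rec$fs, interval_s = interval_s)
  parcel_epochs <- lapply(ivs, average_by_parcel, parcel_map = pm)
  coh <- coherence_matrix(parcel_epochs, fs = rec$fs, fmin = fmin,
                          fmax = fmax)
  edges <- do.call(rbind, lapply(names(coh$intervals), function(nm) {
    top_k_edges(coh, k = k, interval = nm, per_band = per_band)
  }))
  structure(
    list(coherence = coh, edges = edges, inverse = fit,
         n_spikes = n_spikes, parcels = coh$parcels,
         settings = list(method = method, alpha = fit$alpha, pre_s = pre_s,
                         post_s = post_s, interval_s = interval_s,
                         fmin = fmin, fmax = fmax, k = k,
                         per_band = per_band, fs = rec$fs)),
    class = "spike_coherence"
  )
}

#' @export
print.spike_coherence <- function(x, ...) {
  cat("Spike-locked source coherence analysis\n")
  cat(sprintf("  %d spikes, inverse: %s (alpha = %.4g)\n", x$n_spikes,
              x$settings$method, x$settings$alpha))
  cat(sprintf("  %d parcels, intervals: %s\n", length(x$parcels),
              paste(names(x$coherence$intervals), collapse = ", ")))
  top <- x$edges[x$edges$interval == "spike", ]
  top <- top[order(-top$coherence), ][seq_len(min(3L, nrow(top))), ]
  cat("  strongest spike-interval edges:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s - %s (%s): %.3f\n", top$parcel_a[i], top$parcel_b[i],
                top$band[i], top$coherence[i]))
  }
  invisible(x)
}

#' @export
summary.spike_coherence <- function(object, ...) {
  summary(object$coherence)
}

#' @export
plot.spike_coherence <- function(x, interval = "spike", band = "alpha", ...) {
  plot(x$coherence, interval = interval, band = band, ...)
}

#' Validate a pipeline configuration
#'
#' A pipeline configuration is a named list (typically read from YAML or
#' JSON) with a `paths` block (`eeg`, `events`, `leadfield`, `parcels`, and
#' optionally `mesh`) and optional analysis settings (`method`, `alpha`,
#' `pre_s`, `post_s`, `interval_s`, `fmin`, `fmax`, `k`, `seed`).
#'
#' @param config a list or path to a YAML/JSON file.
#' @return The validated, default-completed configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- list(method = "csl", alpha = "gcv", pre_s = 1.5, post_s = 1.5,
                   interval_s = 1, fmin = 1, fmax = 70, k = 100,
                   per_band = TRUE, seed = 1L)
  config <- modifyList(defaults, config)
  if (!config$method %in% c("csl", "minimum_norm")) {
    stop("validation error in field 'method': unknown inverse method '",
         config$method, "' (expected 'csl' or 'minimum_norm')")
  }
  if (config$fmin < 1 || config$fmax > 1000 || config$fmin >= config$fmax) {
    stop("validation error in fields 'fmin'/'fmax'")
  }
  need <- c("eeg", "events", "leadfield", "parcels")
  if (is.null(config$paths) || !all(need %in% names(config$paths))) {
    stop("validation error in field 'paths': need ",
         paste(need, collapse = ", "))
  }
  for (nm in need) {
    if (!file.exists(config$paths[[nm]])) {
      stop("validation error in field 'paths$", nm, "': file not found: ",
           config$paths[[nm]])
    }
  }
  config
}

#' Run the end-to-end pipeline from files
#'
#' Reads the configured inputs (EDF recording, events TSV, lead-field TSV,
#' parcel table, optional mesh with a Laplacian rebuilt from its
#' tessellation -- or a precomputed Laplacian triple file), runs
#' [spike_coherence()], and writes the result bundle: band coherence
#' matrices, edge lists, the band mapping table, and a provenance JSON
#' (configuration, input hashes, package version, seed).
#'
#' @param config configuration list or YAML/JSON path (see
#'   [pipeline_config()]).
#' @param out_dir output directory.
#' @return The [spike_coherence()] object, invisibly, with `files`
#'   attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  events <- stage("events", read_events(config$paths$events))
  rec <- stage("read_eeg",
               read_edf(config$paths$eeg, spike_times = events$onset_s))
  K <- stage("leadfield", read_leadfield(config$paths$leadfield))
  pm <- stage("parcels", read_parcel_map(config$paths$parcels))
  W <- NULL
  if (config$method == "csl") {
    W <- stage("laplacian", {
      if (!is.null(config$paths$laplacian)) {
        tr <- read.delim(config$paths$laplacian)
        Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$value,
                             dims = rep(ncol(K), 2L))
      } else if (!is.null(config$paths$mesh)) {
        mesh <- read_mesh(config$paths$mesh)
        target <- mesh_area(mesh) / ncol(K)
        tess <- tessellate_patches(mesh, target_area = target,
                                   seed = config$seed %||% 0L)
        if (tess$n_patches != ncol(K)) {
          stop("mesh tessellation yields ", tess$n_patches,
               " patches but the lead field has ", ncol(K))
        }
        build_laplacian(tess$neighbors)
      } else {
        stop("method 'csl' needs paths$laplacian or paths$mesh")
      }
    })
  }
  res <- stage("analysis", spike_coherence(
    rec, K, W = W, parcel_map = pm, method = config$method,
    alpha = config$alpha, pre_s = config$pre_s, post_s = config$post_s,
    interval_s = config$interval_s, fmin = config$fmin, fmax = config$fmax,
    k = config$k, per_band = config$per_band
  ))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_coherence(res$coherence, file.path(out_dir, "coherence"),
                           k = config$k)
  fe <- file.path(out_dir, "edges.tsv")
  write.table(res$edges, fe, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(
    package = "epicoh",
    version = as.character(utils::packageVersion("epicoh")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config[setdiff(names(config), "paths")],
    inputs = lapply(config$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_spikes = res$n_spikes,
    alpha = res$settings$alpha
  )
  fp <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, fp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(res, "files") <- c(files, fe, fp)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
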