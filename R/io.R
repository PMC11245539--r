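#' Run manifest
#'
#' Metadata identifying a run: the configuration digest, the master seed and
#' the derived per-module child seeds, package version and timestamp.
#' Recordings carrying the same manifest are bit-identical on re-run.
#'
#' @param cfg a [flex_config()].
#' @param seed master seed.
#' @return A named list.
#' @export
run_manifest <- function(cfg, seed) {
  streams <- c("build", "baseline", "trial:1", "rnn-weights")
  list(config_hash = config_hash(cfg),
       master_seed = seed,
       child_seeds = stats::setNames(
         lapply(streams, function(s) child_seed(seed, s)), streams),
       package_version = as.character(utils::packageVersion("flexsim")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Save a session recording to a directory
#'
#' Writes the recording as plain columnar tables — `spikes.csv` (trial,
#' time_ms, population, neuron_id), `rates.csv` (long format), `D.csv` and
#' `weights.csv` — plus `manifest.json` with the config digest, seed and
#' package version.  Floats are written with 17 significant digits so the
#' round trip reproduces them exactly.
#'
#' @param session a `flex_session`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
save_recording <- function(session, path) {
  stopifnot(inherits(session, "flex_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(session$rates)[3]
  steps <- dim(session$rates)[1]
  pops <- dimnames(session$rates)[[2]]

  sp <- session$spikes
  if (is.null(sp)) {
    sp <- data.frame(trial = integer(0), time_ms = numeric(0),
                     population = character(0), neuron_id = integer(0))
  }
  utils::write.csv(sp[c("trial", "time_ms", "population", "neuron_id")],
                   file.path(path, "spikes.csv"), row.names = FALSE)

  rates_long <- data.frame(
    trial = rep(seq_len(nt), each = steps * length(pops)),
    time_ms = rep(rep((seq_len(steps) - 1) * session$dt, times = length(pops)),
                  times = nt),
    population = rep(rep(pops, each = steps), times = nt),
    rate = fmt_num(as.numeric(session$rates)))
  utils::write.csv(rates_long, file.path(path, "rates.csv"),
                   row.names = FALSE)

  Dlong <- data.frame(
    trial = rep(seq_len(nt), each = steps),
    time_ms = rep((seq_len(steps) - 1) * session$dt, times = nt),
    D = fmt_num(as.numeric(session$D)))
  if (!is.null(session$A)) Dlong$A <- fmt_num(as.numeric(session$A))
  utils::write.csv(Dlong, file.path(path, "D.csv"), row.names = FALSE)

  wc <- session$weight_curves
  wc$mean_weight <- fmt_num(wc$mean_weight)
  utils::write.csv(wc, file.path(path, "weights.csv"), row.names = FALSE)

  manifest <- run_manifest(session$network$config, session$seed)
  manifest$n_trials <- nt
  manifest$trial_length <- session$protocol$trial_length
  manifest$dt <- session$dt
  manifest$populations <- pops
  manifest$has_A <- !is.null(session$A)
  manifest$files <- lapply(
    c("spikes.csv", "rates.csv", "D.csv", "weights.csv"),
    function(f) unname(tools::md5sum(file.path(path, f))))
  names(manifest$files) <- c("spikes.csv", "rates.csv", "D.csv",
                             "weights.csv")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a recording saved by [save_recording()]
#'
#' Refuses to load a directory without a manifest, and verifies the file
#' digests recorded in it before parsing (a mismatch raises an integrity
#' error).
#'
#' @param path directory written by [save_recording()].
#' @return A list with `spikes`, `rates` (steps x populations x trials
#'   array), `D`, `A` (or `NULL`), `weight_curves`, `manifest`.
#' @export
load_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("no manifest.json in '", path,
         "': refusing to load an unidentified recording", call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    found <- unname(tools::md5sum(file.path(path, f)))
    if (!identical(found, manifest$files[[f]])) {
      stop("integrity error: digest mismatch for ", f, call. = FALSE)
    }
  }
  spikes <- utils::read.csv(file.path(path, "spikes.csv"))
  rates_long <- utils::read.csv(file.path(path, "rates.csv"))
  Dlong <- utils::read.csv(file.path(path, "D.csv"))
  wc <- utils::read.csv(file.path(path, "weights.csv"))

  nt <- manifest$n_trials
  pops <- manifest$populations
  steps <- nrow(Dlong) / nt
  rates <- array(as.numeric(rates_long$rate),
                 c(steps, length(pops), nt),
                 dimnames = list(NULL, pops, NULL))
  D <- matrix(as.numeric(Dlong$D), steps, nt)
  A <- if (isTRUE(manifest$has_A)) matrix(as.numeric(Dlong$A), steps, nt)
  list(spikes = spikes, rates = rates, D = D, A = A,
       weight_curves = wc, manifest = manifest)
}
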