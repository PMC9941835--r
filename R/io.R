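#' Read and write sweep bundles
#'
#' A bundle is stored as a directory containing `metadata.json` (family
#' kind, sampling rate, capacitance, per-sweep metadata) and one CSV per
#' sweep with columns `t_ms`, `v_mV`, `i_pA`. Numbers are written at full
#' double precision so that `read_bundle(write_bundle(x))` round-trips the
#' arrays bit-for-bit within float formatting.
#'
#' @param bundle A `cav_bundle`.
#' @param path Directory to create (must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing directory?
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()`
#'   returns a `cav_bundle`.
#' @export
write_bundle <- function(bundle, path, overwrite = FALSE) {
  stopifnot(inherits(bundle, "cav_bundle"))
  if (dir.exists(path)) {
    if (!overwrite) stop("path exists; use overwrite = TRUE")
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  files <- sprintf("sweep_%03d.csv", seq_along(bundle$sweeps))
  meta <- list(
    family_kind = bundle$family_kind,
    meta = bundle$meta,
    sampling_rate_hz = attr(bundle$sweeps[[1]], "sampling_rate_hz"),
    capacitance_pF = attr(bundle$sweeps[[1]], "capacitance_pF"),
    sweeps = purrr::imap(bundle$sweeps, function(s, k) {
      c(list(file = files[k]), attr(s, "meta"))
    }))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  purrr::walk2(bundle$sweeps, files, function(s, f) {
    con <- file(file.path(path, f), "w")
    on.exit(close(con))
    writeLines("t_ms,v_mV,i_pA", con)
    writeLines(paste(sprintf("%.17g", s$t_ms), sprintf("%.17g", s$v_mV),
                     sprintf("%.17g", s$i_pA), sep = ","), con)
  })
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  mfile <- file.path(path, "metadata.json")
  if (!file.exists(mfile)) stop("not a bundle: missing metadata.json")
  meta <- jsonlite::read_json(mfile, simplifyVector = FALSE)
  for (f in c("family_kind", "sampling_rate_hz", "capacitance_pF", "sweeps")) {
    if (is.null(meta[[f]])) stop("bundle schema violation: missing '", f, "'")
  }
  sweeps <- purrr::map(meta$sweeps, function(sm) {
    if (is.null(sm$file)) stop("bundle schema violation: missing 'sweeps.file'")
    df <- utils::read.csv(file.path(path, sm$file),
                          colClasses = "numeric")
    if (!identical(names(df), c("t_ms", "v_mV", "i_pA"))) {
      stop("bundle schema violation: bad columns in ", sm$file)
    }
    sm$file <- NULL
    new_sweep(tibble::as_tibble(df),
              sampling_rate_hz = meta$sampling_rate_hz,
              capacitance_pF = meta$capacitance_pF,
              meta = sm)
  })
  new_bundle(sweeps, meta$family_kind, meta = meta$meta)
}

#' Read and validate a run configuration
#'
#' A YAML configuration describes one simulation/analysis run: a preset
#' label or explicit gating parameters, the cell model, a protocol family
#' specification, analysis options and the seed. Unknown keys are rejected
#' with their path, so typos fail before any computation.
#'
#' @param path Path to a YAML file.
#' @return A list with components `gating` ([gating_params()]), `cell`
#'   ([cell_model()]), `drug` ([drug_model()] or `NULL`), `protocol` (list
#'   spec as given), `analysis` (options list), `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("preset", "gating", "cell", "drug", "protocol",
                    "analysis", "seed", "output"), "")
  if (is.null(cfg$preset) && is.null(cfg$gating)) {
    stop("config must give either 'preset' or 'gating'")
  }
  gating <- if (!is.null(cfg$gating)) {
    check_keys(cfg$gating,
               c("label", "v05_act", "k_act", "v_rev", "gmax_density",
                 "tau_act", "v05_inact", "k_inact", "frac_noninact",
                 "a_fast", "a_slow", "tau_inact_fast", "tau_inact_slow",
                 "tau_rec_fast", "tau_rec_slow", "tau_deact_ref", "hook"),
               "gating")
    do.call(gating_params, cfg$gating)
  } else preset_gating(cfg$preset)
  cell <- if (!is.null(cfg$cell)) {
    check_keys(cfg$cell, c("capacitance_pF", "leak_nS", "noise_sd_pA",
                           "rundown_pct_per_min", "seed"), "cell")
    do.call(cell_model, cfg$cell)
  } else if (!is.null(cfg$preset)) preset_cell(cfg$preset) else cell_model()
  drug <- if (!is.null(cfg$drug)) {
    check_keys(cfg$drug, c("ic50_nM", "hill_slope", "equilibration_tau_s"),
               "drug")
    do.call(drug_model, cfg$drug)
  }
  if (!is.null(cfg$protocol)) {
    check_keys(cfg$protocol,
               c("kind", "v_test", "hp", "v_start", "v_stop", "step",
                 "pulse_ms", "gaps_s", "repol_voltages", "cond_start",
                 "cond_stop", "sampling_rate_hz"),
               "protocol")
  }
  list(gating = gating, cell = cell, drug = drug,
       protocol = cfg$protocol, analysis = cfg$analysis %||% list(),
       seed = cfg$seed %||% 1L, output = cfg$output)
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(if (nzchar(where)) paste0(where, "."), bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
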