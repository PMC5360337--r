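# Flat key-value run configuration shared by the CLI and the scripts.
# One "key = value" pair per line, '#' comments; unknown keys are an error.

config_defaults <- function() {
  p <- model_params()
  list(
    # model block (field names match model_params)
    n_sites = p$n_sites, spacing_a = p$spacing_a, epsilon = p$epsilon,
    decay_length_lambda = p$decay_length_lambda, contact_r0 = p$contact_r0,
    kernel = p$kernel, alphabet_size = p$alphabet_size,
    theta_max = p$theta_max, n_angle_bins = p$n_angle_bins,
    k_rot = p$k_rot, k_off0 = p$k_off0,
    # ensemble block
    q = 1 / p$alphabet_size, genome = "", genome_length = 4641652,
    n_replicates = 2000L, master_seed = 1L,
    # proofreading block
    target_fraction = 0.99, tau_diff = 0, k = 1L, include_N0 = FALSE,
    # output
    out_dir = "."
  )
}

#' Default run configuration
#'
#' All-defaults configuration: the standard rod geometry (17 sites, 3.4 nm
#' spacing), `epsilon = 1.5` kBT, `theta_max = pi/2`, `q = 1/4`, and an
#' E. coli-sized random genome.
#'
#' @return A named list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(config_defaults(), class = "run_config")
}

#' Load a run configuration from a flat key-value file
#'
#' Lines have the form `key = value`; blank lines and `#` comments are
#' ignored.  Every key must be one of the documented configuration fields;
#' unknown keys are a hard error.  Missing keys take their defaults.
#'
#' @param path Path to the configuration file.  An empty file yields the
#'   all-defaults configuration.
#' @return A validated `"run_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path, call. = FALSE)
  defaults <- config_defaults()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected 'key = value'): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults))
      stop("unknown config key: ", key, call. = FALSE)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.logical(proto)) {
      if (!toupper(val) %in% c("TRUE", "FALSE", "T", "F"))
        stop("config key ", key, " must be TRUE/FALSE, got: ", val, call. = FALSE)
      as.logical(toupper(val))
    } else if (is.integer(proto)) {
      iv <- suppressWarnings(as.integer(val))
      if (is.na(iv)) stop("config key ", key, " must be an integer, got: ", val,
                          call. = FALSE)
      iv
    } else if (is.numeric(proto)) {
      nv <- suppressWarnings(as.numeric(val))
      if (is.na(nv)) stop("config key ", key, " must be numeric, got: ", val,
                          call. = FALSE)
      nv
    } else val
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  # range checks on the model block reuse the params validator
  config_params(cfg)
  if (cfg$q <= 0 || cfg$q > 1) stop("q must lie in (0, 1]", call. = FALSE)
  if (cfg$genome_length < 1) stop("genome_length must be >= 1", call. = FALSE)
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (cfg$target_fraction <= 0 || cfg$target_fraction > 1)
    stop("target_fraction must lie in (0, 1]", call. = FALSE)
  if (cfg$tau_diff < 0) stop("tau_diff must be >= 0", call. = FALSE)
  if (cfg$k < 1) stop("k must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Model parameters carried by a run configuration
#'
#' @param cfg A `"run_config"` list.
#' @return The embedded [model_params()] object.
#' @export
config_params <- function(cfg) {
  model_params(n_sites = cfg$n_sites, spacing_a = cfg$spacing_a,
               epsilon = cfg$epsilon,
               decay_length_lambda = cfg$decay_length_lambda,
               contact_r0 = cfg$contact_r0, kernel = cfg$kernel,
               alphabet_size = cfg$alphabet_size, theta_max = cfg$theta_max,
               n_angle_bins = cfg$n_angle_bins, k_rot = cfg$k_rot,
               k_off0 = cfg$k_off0)
}

#' Write a run configuration to a flat key-value file
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param cfg A `"run_config"` list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
    if (is.numeric(v)) return(format(v, digits = 17))
    as.character(v)
  }
  lines <- vapply(names(config_defaults()),
                  function(k) sprintf("%s = %s", k, fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

# TSV writer with a '#'-prefixed comment header recording parameters; the
# body is byte-stable for identical inputs (timestamps stay in comments).
write_tsv_commented <- function(df, path, params = NULL, extra = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# written by rodsearch on ", format(Sys.time(), "%Y-%m-%d")),
             con)
  if (!is.null(params)) {
    for (k in setdiff(names(params), "kernel_cache"))
      if (is.atomic(params[[k]]))
        writeLines(sprintf("# %s = %s", k, format(params[[k]], digits = 15)), con)
  }
  for (e in extra) writeLines(paste0("# ", e), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write deterministic test fixtures
#'
#' Three kinds: `toy_genome` (a synthetic FASTA of i.i.d. uniform bases),
#' `sequence_panel` (off-target sequences for every class `N` with a
#' manifest TSV), and `toy_chain` (a small hand-rated chain edge list whose
#' mean unbinding time from first-step analysis is stored in the manifest).
#' Identical seed and size give byte-identical files.
#'
#' @param kind One of `"toy_genome"`, `"sequence_panel"`, `"toy_chain"`.
#' @param seed Integer seed.
#' @param size `toy_genome`: number of bases (<= 1e6); `sequence_panel`:
#'   replicates per class (<= 1000); ignored for `toy_chain`.
#' @param dir Output directory (created if needed).
#' @param params A [model_params()] object (sequence panel geometry).
#' @param overwrite Allow clobbering existing files.
#' @return Character vector of the files written.
#' @export
make_fixture <- function(kind = c("toy_genome", "sequence_panel", "toy_chain"),
                         seed = 1L, size = 1000L, dir = ".",
                         params = model_params(), overwrite = FALSE) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f) && !overwrite)
      stop("fixture exists (use overwrite = TRUE): ", f, call. = FALSE)
    f
  }
  if (kind == "toy_genome") {
    if (size < 1 || size > 1e6) stop("toy_genome size must be in [1, 1e6]",
                                     call. = FALSE)
    set.seed(seed)
    bases <- sample(c("A", "C", "G", "T"), size, replace = TRUE)
    f <- outfile(sprintf("toy_genome_seed%d_n%d.fasta", seed, size))
    con <- file(f, "wt")
    writeLines(sprintf(">synthetic_random_genome seed=%d length=%d", seed, size),
               con)
    writeLines(vapply(split(bases, ceiling(seq_along(bases) / 70)),
                      paste0, character(1), collapse = ""), con)
    close(con)
    return(f)
  }
  if (kind == "sequence_panel") {
    if (size < 1 || size > 1000) stop("sequence_panel size must be in [1, 1000]",
                                      call. = FALSE)
    n <- params$n_sites
    set.seed(seed)
    target <- random_sequence(n, params$alphabet_size)
    rows <- list()
    for (N in 0:n) for (r in seq_len(size)) {
      pp <- offtarget_with_N_matches(target, N,
                                     alphabet_size = params$alphabet_size)
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, replicate = r,
        partner = paste(pp$seq_b, collapse = ","),
        reclassified_N = central_run_length(pp))
    }
    f <- outfile(sprintf("sequence_panel_seed%d.tsv", seed))
    write_tsv_commented(do.call(rbind, rows), f, params = params,
                        extra = sprintf("target = %s",
                                        paste(target, collapse = ",")))
    return(f)
  }
  # toy_chain: 3 bound states + UNBOUND with fixed hand-set rates.
  # First-step analysis for the mean time to UNBOUND from state 1:
  # solve (-Q) tau = 1 by hand on the 3x3 system below.
  rates <- data.frame(
    state_from = c("s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    state_to   = c("s2", "UNBOUND", "s1", "s3", "UNBOUND", "s2", "UNBOUND"),
    rate       = c(2.0, 0.5, 1.0, 1.0, 0.25, 3.0, 1.5))
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 2; Q[2, 1] <- 1; Q[2, 3] <- 1; Q[3, 2] <- 3
  u <- c(0.5, 0.25, 1.5)
  diag(Q) <- -(rowSums(Q) + u)
  tau <- solve(-Q, rep(1, 3))
  f <- outfile(sprintf("toy_chain_seed%d.tsv", seed))
  write_tsv_commented(rates, f,
                      extra = c("states = s1 s2 s3 (+ absorbing UNBOUND)",
                                sprintf("mfpt_from_s1 = %.12g", tau[1]),
                                sprintf("mfpt_from_s2 = %.12g", tau[2]),
                                sprintf("mfpt_from_s3 = %.12g", tau[3])))
  f
}
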