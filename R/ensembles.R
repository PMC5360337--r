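#' Draw a random site sequence
#'
#' Sites are i.i.d. uniform over an alphabet of `alphabet_size` symbols, so
#' two independently drawn sites match accidentally with probability
#' `q = 1/alphabet_size`.
#'
#' @param length Number of sites.
#' @param alphabet_size Number of symbols, at least 2.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Integer vector of symbols in `1:alphabet_size`.
#' @export
random_sequence <- function(length, alphabet_size, rng_seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (alphabet_size < 2L) stop("alphabet_size must be >= 2", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sample.int(alphabet_size, length, replace = TRUE)
}

# Draw a symbol different from `sym`, uniformly over the rest of the alphabet.
mismatch_symbol <- function(sym, alphabet_size) {
  r <- sample.int(alphabet_size - 1L, length(sym), replace = TRUE)
  ifelse(r >= sym, r + 1L, r)
}

# Run of matched sites containing the central site; span [lo, hi] 1-based.
central_run_span <- function(N, n_sites) {
  cc <- central_site(n_sites)
  if (N == 0L) return(c(lo = cc, hi = cc - 1L))  # empty span
  lo <- cc - (N - 1L) %/% 2L      # even N extends one extra site rightwards
  hi <- cc + N %/% 2L
  c(lo = lo, hi = hi)
}

#' Off-target partner with exactly N central matches
#'
#' Builds a partner sequence whose maximal run of sites matching `target`
#' and containing the central site (the collision point) has length exactly
#' `N`.  The run is placed as symmetrically as possible about the center
#' (even `N` extends one extra site to the right); the sites immediately
#' outside the run are forced to mismatch so the off-target classes are
#' disjoint; every remaining site matches the target independently with
#' probability `q`.  `N = 0` forces a central mismatch; `N = n_sites`
#' returns the target itself.
#'
#' @param target Integer site sequence (symbols in `1:alphabet_size`), odd
#'   length.
#' @param N Required central match-run length, `0 <= N <= length(target)`.
#' @param q Accidental per-site match probability for the free sites;
#'   defaults to `1/alphabet_size`.
#' @param rng_seed Optional integer seed.
#' @param alphabet_size Alphabet size used to draw mismatching symbols.
#' @return A [site_pairing()] of `target` with the constructed partner.
#' @export
offtarget_with_N_matches <- function(target, N, q = 1 / alphabet_size,
                                     rng_seed = NULL, alphabet_size = 4L) {
  n <- length(target)
  if (N < 0L || N > n) stop("N must lie in [0, n_sites]", call. = FALSE)
  if (alphabet_size < 2L) stop("alphabet_size must be >= 2", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (N == n) return(site_pairing(target, target))
  span <- central_run_span(N, n)
  partner <- integer(n)
  run <- if (N > 0L) span["lo"]:span["hi"] else integer(0)
  partner[run] <- target[run]
  border <- c(if (span["lo"] > 1L) span["lo"] - 1L,
              if (span["hi"] < n) span["hi"] + 1L)
  if (N == 0L) border <- central_site(n)   # only the central mismatch is forced
  partner[border] <- mismatch_symbol(target[border], alphabet_size)
  free <- setdiff(seq_len(n), c(run, border))
  if (length(free) > 0L) {
    hit <- runif(length(free)) < q
    partner[free[hit]] <- target[free[hit]]
    if (any(!hit))
      partner[free[!hit]] <- mismatch_symbol(target[free[!hit]], alphabet_size)
  }
  site_pairing(target, partner)
}

#' Near-target partner with M forced central mismatches
#'
#' The partner equals `target` everywhere except at `M` sites centered on
#' the collision point (even `M` extends one extra site to the right),
#' which are forced to mismatch.  `M = 0` returns the perfect match.
#'
#' @param target Integer site sequence, odd length.
#' @param M Number of forced central mismatches, `0 <= M <= length(target)`.
#' @param rng_seed Optional integer seed.
#' @param alphabet_size Alphabet size used to draw mismatching symbols.
#' @return A [site_pairing()].
#' @export
target_with_M_central_mismatches <- function(target, M, rng_seed = NULL,
                                             alphabet_size = 4L) {
  n <- length(target)
  if (M < 0L || M > n) stop("M must lie in [0, n_sites]", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  partner <- target
  if (M > 0L) {
    span <- central_run_span(M, n)
    idx <- span["lo"]:span["hi"]
    partner[idx] <- mismatch_symbol(target[idx], alphabet_size)
  }
  site_pairing(target, partner)
}

#' Central match-run length of a pairing
#'
#' Length of the maximal run of matched facing sites containing the central
#' site; 0 if the central site mismatches.  This is the classifier that
#' defines the off-target classes.
#'
#' @param x A [site_pairing()], or a logical vector of facing-site matches.
#' @return Integer run length `N` in `0:n_sites`.
#' @export
central_run_length <- function(x) {
  m <- if (inherits(x, "site_pairing")) diag(x$match) else as.logical(x)
  n <- length(m)
  cc <- central_site(n)
  if (!m[cc]) return(0L)
  lo <- cc
  while (lo > 1L && m[lo - 1L]) lo <- lo - 1L
  hi <- cc
  while (hi < n && m[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

new_ensemble_stats <- function(q, f, f_T = 1, genome_length = NA_real_,
                               source = "random") {
  structure(list(q = q, f = f, f_T = f_T,
                 genome_length = genome_length, source = source),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble_stats (%s): q = %.4g, genome length %s, f_T = %g\n",
              x$source, x$q, format(x$genome_length, big.mark = ","), x$f_T))
  print(round(x$f, 4))
  invisible(x)
}

#' Expected match-run class frequencies for a random genome
#'
#' Closed-form expected number `f[N]` of genome segments whose pairing with
#' a searcher has a central match-run of exactly `N` sites, under i.i.d.
#' accidental matches with probability `q`.  A run of length `N` covering
#' sites `[c-l, c+r]` occurs with probability `q^N` times a `(1-q)` factor
#' for each bounding mismatch, omitted where the run reaches a rod end.
#' The `f[N]` sum exactly to `genome_length`: every segment falls in
#' exactly one class.
#'
#' @param params A [model_params()] object (odd `n_sites`).
#' @param genome_length Number of segments `G` in the genome.
#' @param q Accidental match probability; defaults to `1/alphabet_size`.
#' @return An `"ensemble_stats"` object with `f` a named vector over
#'   `N = 0:n_sites` of expected counts.
#' @export
fN_random <- function(params, genome_length, q = 1 / params$alphabet_size) {
  if (genome_length < 1) stop("genome_length must be >= 1", call. = FALSE)
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]", call. = FALSE)
  n <- params$n_sites
  cc <- central_site(n)
  Lmax <- cc - 1L
  Rmax <- n - cc
  pr <- numeric(n + 1L)          # index N + 1
  pr[1] <- 1 - q
  for (N in seq_len(n)) {
    tot <- 0
    for (l in max(0L, N - 1L - Rmax):min(Lmax, N - 1L)) {
      r <- N - 1L - l
      bl <- if (l < Lmax) 1 - q else 1
      br <- if (r < Rmax) 1 - q else 1
      tot <- tot + q^N * bl * br
    }
    pr[N + 1L] <- tot
  }
  f <- genome_length * pr
  names(f) <- 0:n
  new_ensemble_stats(q, f, f_T = 1, genome_length = genome_length,
                     source = sprintf("random q=%g", q))
}

#' Empirical match-run class frequencies from a genome
#'
#' Slides a window of `n_sites` symbols over each FASTA record (step 1) and
#' classifies every window by the central match-run length of its pairing
#' with `searcher`.  Each nucleotide-level window stands in for one
#' potential collision partner of the searcher.  Windows containing
#' ambiguity codes are skipped and counted.
#'
#' @param genome Path to a FASTA file over A/C/G/T (multi-record allowed;
#'   windows do not span record boundaries).
#' @param searcher Searcher sequence: integer vector over 1:4 (A, C, G, T)
#'   or a character string of nucleotides, length `n_sites`.
#' @param params A [model_params()] object (odd `n_sites`).
#' @param include_revcomp If `TRUE`, windows of the reverse-complement
#'   strand are classified as well (total classified windows doubles on a
#'   palindrome-free genome).
#' @return An `"ensemble_stats"` object; counts of windows per class in
#'   `f`, skipped-window count in attribute `"n_skipped"`.
#' @export
fN_genome <- function(genome, searcher, params, include_revcomp = FALSE) {
  if (!file.exists(genome))
    stop("cannot read genome FASTA: ", genome, call. = FALSE)
  recs <- Biostrings::readDNAStringSet(genome)
  if (length(recs) == 0L) stop("no FASTA records in ", genome, call. = FALSE)
  searcher <- as_site_ints(searcher)
  n <- params$n_sites
  if (length(searcher) != n)
    stop("searcher length must equal n_sites", call. = FALSE)
  if (max(vapply(recs, length, integer(1))) < n)
    stop("genome shorter than n_sites", call. = FALSE)
  counts <- setNames(numeric(n + 1L), 0:n)
  n_skipped <- 0L
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (r in seq_along(recs)) {
    chars <- strsplit(as.character(recs[[r]]), "")[[1]]
    g <- unname(code[chars])     # ambiguity codes become NA
    strands <- list(g)
    if (include_revcomp) strands <- c(strands, list(5L - rev(g)))
    for (gs in strands) {
      W <- length(gs) - n + 1L
      if (W < 1L) next
      ok <- !is.na(gs)
      okw <- rep(TRUE, W)
      mm <- matrix(FALSE, W, n)
      for (i in seq_len(n)) {
        idx <- i:(i + W - 1L)
        okw <- okw & ok[idx]
        mm[, i] <- gs[idx] == searcher[i]
      }
      n_skipped <- n_skipped + sum(!okw)
      mm[is.na(mm)] <- FALSE
      Ns <- classify_runs_matrix(mm[okw, , drop = FALSE])
      tab <- tabulate(Ns + 1L, nbins = n + 1L)
      counts <- counts + tab
    }
  }
  out <- new_ensemble_stats(1 / params$alphabet_size, counts, f_T = 1,
                            genome_length = sum(counts),
                            source = paste0("genome:", basename(genome)))
  attr(out, "n_skipped") <- n_skipped
  out
}

# Vectorized central-run classifier over rows of a logical match matrix.
classify_runs_matrix <- function(mm) {
  W <- nrow(mm)
  if (W == 0L) return(integer(0))
  n <- ncol(mm)
  cc <- central_site(n)
  left <- integer(W)
  run <- rep(TRUE, W)
  for (k in seq_len(cc - 1L)) {
    run <- run & mm[, cc - k]
    left <- left + run
  }
  right <- integer(W)
  run <- rep(TRUE, W)
  for (k in seq_len(n - cc)) {
    run <- run & mm[, cc + k]
    right <- right + run
  }
  ifelse(mm[, cc], left + right + 1L, 0L)
}

# Accept integer site vectors or nucleotide strings.
as_site_ints <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
    v <- unname(code[strsplit(toupper(x), "")[[1]]])
    if (anyNA(v)) stop("searcher contains non-ACGT symbols", call. = FALSE)
    return(v)
  }
  as.integer(x)
}

#' Export ensemble statistics as TSV
#'
#' @param stats An `"ensemble_stats"` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ensemble_stats <- function(stats, path) {
  df <- data.frame(N = as.integer(names(stats$f)),
                   count = unname(stats$f),
                   frequency = unname(stats$f) / sum(stats$f))
  write_tsv_commented(df, path,
                      extra = c(sprintf("q = %g", stats$q),
                                sprintf("source = %s", stats$source)))
}
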