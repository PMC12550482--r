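#' Pipeline parameters
#'
#' Bundle of the tuning constants used across indexing, cleaning and read
#' assignment.  Defaults are the values used throughout this package:
#' `k = 34` with `z = 3` composite s-mers (`s = k - z + 1 = 32`), a per-filter
#' false-positive target of `fp = 0.05` (so the per-k-mer query rate is about
#' `fp^z = 1.25e-4`), an acceptance cutoff `t_c = 0.7` on the best shared
#' k-mer proportion, a near-best window `delta = 0.1`, and an abundance
#' cutoff of 1e-5 (`r`) expressed as a fraction of all queried reads.
#'
#' @param k k-mer length in bases used for query scoring.
#' @param z number of neighbouring s-mers tested per k-mer; `1 <= z < k`.
#' @param fp per-filter false-positive target, in (0, 1).
#' @param t_c cutoff proportion of shared k-mers for a positive match.
#' @param delta window below the best proportion defining near-best entries;
#'   `0 <= delta < t_c`.
#' @param r minimum fraction of total queried reads a taxon must receive to
#'   be retained; `0 <= r < 1`.
#' @param seed hash seed recorded in every filter (reproducibility).
#' @param backend `"bloom"` for the probabilistic bit-field backend, or
#'   `"exact"` for a hash-set backend with identical interface (used as the
#'   truth oracle in tests).
#'
#' @return An object of class `skim_params`: a named list with the fields
#'   above plus the derived s-mer length `s`.
#' @examples
#' p <- skim_params()
#' p$s  # 32
#' @export
skim_params <- function(k = 34L, z = 3L, fp = 0.05, t_c = 0.7, delta = 0.1,
                        r = 1e-5, seed = 1L, backend = c("bloom", "exact")) {
  backend <- match.arg(backend)
  k <- as.integer(k)
  z <- as.integer(z)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (is.na(z) || z < 1L || z >= k) stop("z must satisfy 1 <= z < k")
  if (!is.numeric(fp) || fp <= 0 || fp >= 1) stop("fp must be in (0, 1)")
  if (!is.numeric(t_c) || t_c <= 0 || t_c > 1) stop("t_c must be in (0, 1]")
  if (!is.numeric(delta) || delta < 0 || delta >= t_c)
    stop("delta must satisfy 0 <= delta < t_c")
  if (!is.numeric(r) || r < 0 || r >= 1) stop("r must be in [0, 1)")
  structure(
    list(k = k, z = z, s = k - z + 1L, fp = fp, t_c = t_c, delta = delta,
         r = r, seed = as.integer(seed), backend = backend),
    class = "skim_params"
  )
}

#' @export
print.skim_params <- function(x, ...) {
  cat(sprintf(
    "skim_params: k=%d z=%d (s=%d) fp=%g t_c=%g delta=%g r=%g backend=%s\n",
    x$k, x$z, x$s, x$fp, x$t_c, x$delta, x$r, x$backend))
  invisible(x)
}
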