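#' Candidate mother wavelets
#'
#' The eleven candidate mother wavelets covered by the registry: Haar,
#' two Daubechies (db5, db37), two Symlets (sym5, sym18), two Coiflets
#' (coif5, coif14), two spline biorthogonal (bior1.3, bior5.5) and two
#' reverse biorthogonal (rbio1.3, rbio5.5) wavelets.  The number after a
#' family prefix is the number of vanishing moments of the analysis
#' wavelet (for the biorthogonal pairs, of the named spline orders).
#'
#' @return Character vector of wavelet names accepted by [wavelet_filters()].
#' @seealso [wavelet_filters()]
#' @export
#' @examples
#' candidate_wavelets()
candidate_wavelets <- function() {
  names(.wavelet_filter_table)
}

#' Look up the discrete filter bank of a mother wavelet
#'
#' A mother wavelet is represented discretely by its two-channel filter
#' bank: the low-pass/high-pass analysis pair (`dec_lo`, `dec_hi`) and the
#' corresponding synthesis pair (`rec_lo`, `rec_hi`).  For orthogonal
#' families (haar/db/sym/coif) the high-pass filter is the quadrature
#' mirror of the low-pass filter and the synthesis filters are the
#' time-reversed analysis filters; the biorthogonal families carry
#' distinct analysis and synthesis pairs (linear phase, at the price of
#' orthogonality).
#'
#' Coefficients come from the standard published constructions
#' (Daubechies extremal phase, least-asymmetric Symlets, Coiflets,
#' B-spline biorthogonal pairs) and satisfy, to numerical precision,
#' `sum(dec_lo) == sqrt(2)`, `sum(dec_hi) == 0` and, for orthogonal
#' wavelets, unit l2 norm and the quadrature-mirror relation.
#'
#' @param name Wavelet name in conventional lowercase form, e.g. `"haar"`,
#'   `"db37"`, `"coif14"`, `"bior1.3"`.  See [candidate_wavelets()].
#' @return An object of class `"wavelet_spec"`: a list with elements
#'   `name`, `family`, `vanishing_moments`, `orthogonal`, and the four
#'   filter coefficient vectors `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`.
#' @export
#' @examples
#' w <- wavelet_filters("db5")
#' length(w$dec_lo)  # 10: Daubechies length = 2 x vanishing moments
wavelet_filters <- function(name) {
  if (inherits(name, "wavelet_spec")) {
    return(name)
  }
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("`name` must be a single wavelet name; see candidate_wavelets()")
  }
  entry <- .wavelet_filter_table[[name]]
  if (is.null(entry)) {
    stop(sprintf(
      "unsupported wavelet '%s'; supported wavelets are: %s",
      name, paste(names(.wavelet_filter_table), collapse = ", ")
    ))
  }
  structure(
    list(
      name = name,
      family = entry$family,
      vanishing_moments = entry$vanishing_moments,
      orthogonal = entry$orthogonal,
      dec_lo = entry$dec_lo,
      dec_hi = entry$dec_hi,
      rec_lo = entry$rec_lo,
      rec_hi = entry$rec_hi
    ),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spec> %s (%s family, %d vanishing moment%s, %s)\n",
    x$name, x$family, x$vanishing_moments,
    if (x$vanishing_moments == 1L) "" else "s",
    if (x$orthogonal) "orthogonal" else "biorthogonal"
  ))
  cat(sprintf("  filter length: %d taps\n", length(x$dec_lo)))
  invisible(x)
}
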