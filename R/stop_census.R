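#' Census in-frame stop codons
#'
#' Counts stop codons in the framed, countable span of a coding sequence.
#' The stop-codon frequency \eqn{f = n_{stop}/n_{codon}} of a decayed
#' proviral reading frame is the raw statistic behind stop-codon-based ERV
#' dating: after endogenization a reading frame accumulates premature stops
#' at a rate governed by the neutral substitution rate, so \eqn{f} carries a
#' time signal.
#'
#' Framing follows [coding_sequence()]: gaps stripped, \code{frame_offset}
#' applied, trailing partial codon ignored, and (by default) the terminal
#' codon excluded so that an authentic ancestral stop is not mistaken for a
#' post-integration mutation. Codons containing non-ACGT symbols are dropped
#' from numerator and denominator.
#'
#' @param seq A [coding_sequence()].
#' @param stop_set Character vector of stop codons; defaults to the standard
#'   genetic code \code{TAA, TAG, TGA}.
#' @return An object of class \code{stop_census}: a list with
#'   \code{n_codons}, \code{n_stops}, \code{frequency} (exact double),
#'   \code{frequency_display} (3 significant figures, as printed in reports),
#'   and \code{stop_positions} (codon indices in the framed span).
#' @examples
#' census_stop_codons(coding_sequence("ATGTAATAG"))
#' @export
census_stop_codons <- function(seq, stop_set = c("TAA", "TAG", "TGA")) {
  stopifnot(inherits(seq, "coding_sequence"), is.character(stop_set))
  cv <- codon_view(seq)
  cv <- cv[cv$countable, , drop = FALSE]
  if (nrow(cv) == 0L)
    stop("empty reading frame: no countable codons in '", seq$id, "'",
         call. = FALSE)
  is_stop <- cv$codon %in% stop_set
  n_codons <- nrow(cv)
  n_stops <- sum(is_stop)
  structure(
    list(id = seq$id,
         n_codons = n_codons,
         n_stops = n_stops,
         frequency = n_stops / n_codons,
         frequency_display = format_sig3(n_stops / n_codons),
         stop_positions = cv$index[is_stop]),
    class = "stop_census"
  )
}

#' @export
print.stop_census <- function(x, ...) {
  cat(sprintf("<stop_census> %s: %d stops / %d codons (frequency %s)\n",
              x$id, x$n_stops, x$n_codons, x$frequency_display))
  invisible(x)
}

# 3-significant-figure display convention for stop frequencies.
format_sig3 <- function(x) {
  format(signif(x, 3), scientific = FALSE, trim = TRUE)
}
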