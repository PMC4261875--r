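#' Neutral substitution model
#'
#' Homogeneous, site- and base-symmetric neutral substitution: every site
#' leaves its current base at total rate \code{rate} (substitutions per site
#' per year) and the replacement base is uniform over the other three. This
#' is the equal-rates (Jukes-Cantor-type) chain, the unique process
#' satisfying independence and symmetry across sites and base types. Its
#' transition probabilities are closed form: after time \eqn{t},
#' \deqn{P(\mathrm{same}) = 1/4 + (3/4) e^{-4 r t / 3},}
#' with the remaining mass split equally over the other three bases.
#'
#' @param rate Substitution rate in substitutions/site/year; the default
#'   2.2e-9 is an average neutral rate for mammalian genomes. 1e-8 is a
#'   deliberate overestimate used in sensitivity analyses of the
#'   "pseudogene effect".
#' @return An object of class \code{neutral_model}.
#' @export
neutral_model <- function(rate = 2.2e-9) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(list(rate = rate), class = "neutral_model")
}

#' @export
print.neutral_model <- function(x, ...) {
  cat(sprintf("<neutral_model> equal-rates chain, rate %g subs/site/year\n",
              x$rate))
  invisible(x)
}

# P(site unchanged) after t years under the equal-rates chain.
p_same <- function(rate, t) 0.25 + 0.75 * exp(-4 * rate * t / 3)

.BASES <- c("A", "C", "G", "T")

#' Evolve a sequence under neutral substitution
#'
#' Draws the end state of every site independently from the equal-rates
#' chain run for \code{t} years (endpoint sampling from the closed-form
#' transition probabilities; distributionally identical to event-by-event
#' simulation and O(sites)). Non-ACGT symbols (gaps, N) are left untouched.
#'
#' @param seq A [coding_sequence()].
#' @param model A [neutral_model()].
#' @param t Time in years, \code{>= 0}.
#' @param seed Optional integer seed for reproducibility.
#' @return A [coding_sequence()] of identical length and framing.
#' @export
evolve_sequence <- function(seq, model, t, seed = NULL) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(model, "neutral_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("time t must be a single non-negative number", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  chars <- strsplit(seq$bases, "")[[1]]
  idx <- match(chars, .BASES)            # NA for gaps/N: untouched
  live <- which(!is.na(idx))
  if (length(live) > 0L && t > 0) {
    ps <- p_same(model$rate, t)
    change <- stats::runif(length(live)) > ps
    if (any(change)) {
      shift <- sample.int(3L, sum(change), replace = TRUE)  # uniform over other 3
      i <- live[change]
      idx[i] <- ((idx[i] - 1L + shift) %% 4L) + 1L
      chars[i] <- .BASES[idx[i]]
    }
  }
  coding_sequence(paste(chars, collapse = ""), id = seq$id,
                  frame_offset = seq$frame_offset,
                  exclude_terminal = seq$exclude_terminal)
}

#' Closed-form expected stop-codon frequency
#'
#' Independent analytic oracle for the simulator: for each countable codon
#' the exact probability of reading as a stop codon after \code{t} years is
#' the product over its three sites of stay/change probabilities of the
#' equal-rates chain, summed over \code{TAA}, \code{TAG}, \code{TGA}; the
#' returned value is the mean over countable codons. As \eqn{t \to \infty}
#' every codon tends to the uniform stationary value 3/64.
#'
#' @inheritParams evolve_sequence
#' @param stop_set Stop codons of the genetic code in force.
#' @return Expected stop-codon frequency (scalar in \code{[0, 1]}).
#' @export
analytic_stop_probability <- function(seq, model, t,
                                      stop_set = c("TAA", "TAG", "TGA")) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(model, "neutral_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("time t must be a single non-negative number", call. = FALSE)
  cv <- codon_view(seq)
  cv <- cv[cv$countable, , drop = FALSE]
  if (nrow(cv) == 0L)
    stop("empty reading frame: no countable codons in '", seq$id, "'",
         call. = FALSE)
  ps <- p_same(model$rate, t)
  pd <- (1 - ps) / 3
  cod_mat <- do.call(rbind, strsplit(cv$codon, ""))
  p_total <- 0
  for (stop_codon in stop_set) {
    tgt <- strsplit(stop_codon, "")[[1]]
    pr <- matrix(pd, nrow = nrow(cod_mat), ncol = 3L)
    for (j in 1:3) pr[cod_mat[, j] == tgt[j], j] <- ps
    p_total <- p_total + pr[, 1] * pr[, 2] * pr[, 3]
  }
  mean(p_total)
}

#' Mutate alignment members in silico ("pseudogene effect" experiment)
#'
#' Applies [evolve_sequence()] to each in-frame member of a set and returns
#' both the mutated nucleotide sequences and their conceptual translations
#' (standard genetic code; stop codons rendered \code{*}, codons containing
#' non-ACGT symbols rendered \code{X}). This reproduces, at the sequence
#' level, the experiment of artificially ageing extant viral genes by tens
#' of millions of years of neutral change before re-inserting them into a
#' protein alignment for external tree inference. Sequences are returned in
#' their original alignment coordinates; no realignment is performed.
#'
#' @param seqs A list of [coding_sequence()] objects (in frame).
#' @param model A [neutral_model()]; a deliberately high rate such as 1e-8
#'   subs/site/year stresses the neutral-change explanation.
#' @param t Time in years.
#' @param seed Optional integer seed; member \code{i} uses \code{seed + i}.
#' @return A list with \code{nucleotide} (list of mutated
#'   [coding_sequence()]s, ids and order preserved) and \code{protein}
#'   (named character vector of amino-acid sequences).
#' @export
mutate_alignment_members <- function(seqs, model, t, seed = NULL) {
  if (inherits(seqs, "coding_sequence")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1), "coding_sequence")))
  mutated <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s_i <- if (is.null(seed)) NULL else as.integer(seed) + i
    mutated[[i]] <- evolve_sequence(seqs[[i]], model, t, seed = s_i)
  }
  prot <- vapply(mutated, translate_frame, character(1))
  names(prot) <- vapply(mutated, `[[`, character(1), "id")
  list(nucleotide = mutated, protein = prot)
}

# Translate the full framed span (all complete codons, terminal included)
# with the standard code; "*" for stops, "X" for ambiguous codons.
translate_frame <- function(seq) {
  full <- seq
  full$exclude_terminal <- FALSE
  cv <- codon_view(full)
  if (nrow(cv) == 0L) return("")
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(cv$countable,
               unname(code[cv$codon]),
               "X")
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
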