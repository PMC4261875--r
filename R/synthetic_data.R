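#' Codon usage profiles
#'
#' A codon usage profile is a probability distribution over the 61 sense
#' codons of the standard genetic code (stop codons are never drawn; they
#' are planted explicitly where needed). The default profile is uniform
#' over the sense codons. A \code{"gc_biased"} preset, with codon
#' probability proportional to \eqn{2^{GC}} of the codon, is provided for
#' sensitivity checks; no analysis in the package depends on a profile
#' matching any real viral gene.
#'
#' @param preset \code{"uniform"} or \code{"gc_biased"}, or a named numeric
#'   vector of probabilities over sense codons.
#' @return An object of class \code{codon_usage}: named probability vector
#'   over the 61 sense codons.
#' @export
codon_usage <- function(preset = "uniform") {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  if (is.numeric(preset)) {
    p <- preset
    if (is.null(names(p)) || !all(names(p) %in% sense))
      stop("custom usage must be named by sense codons", call. = FALSE)
    full <- stats::setNames(rep(0, length(sense)), sense)
    full[names(p)] <- p
    if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
      stop("usage probabilities must be non-negative and sum to 1",
           call. = FALSE)
    return(structure(full, class = "codon_usage"))
  }
  p <- switch(match.arg(preset, c("uniform", "gc_biased")),
    uniform = stats::setNames(rep(1 / length(sense), length(sense)), sense),
    gc_biased = {
      gc <- vapply(strsplit(sense, ""), function(b) sum(b %in% c("G", "C")),
                   numeric(1))
      w <- 2^gc
      stats::setNames(w / sum(w), sense)
    })
  structure(p, class = "codon_usage")
}

#' Generate a synthetic coding sequence with planted stop codons
#'
#' Draws \code{n_codons} sense codons i.i.d. from a codon usage profile,
#' replaces \code{n_stops_planted} of them (at uniformly chosen positions)
#' with uniformly chosen stop codons, and appends a terminal stop codon.
#' With the default framing (\code{exclude_terminal = TRUE}) a census of the
#' output returns exactly \code{(n_stops_planted, n_codons)}.
#'
#' @param n_codons Number of countable codons.
#' @param usage A [codon_usage()] profile.
#' @param n_stops_planted Number of in-frame stops to plant
#'   (\code{<= n_codons}).
#' @param seed Optional integer seed.
#' @param id Sequence identifier.
#' @return A [coding_sequence()].
#' @export
make_coding_sequence <- function(n_codons, usage = codon_usage(),
                                 n_stops_planted = 0L, seed = NULL,
                                 id = "synthetic") {
  stopifnot(inherits(usage, "codon_usage"))
  n_codons <- as.integer(n_codons)
  n_stops_planted <- as.integer(n_stops_planted)
  if (n_codons < 1L) stop("n_codons must be >= 1", call. = FALSE)
  if (n_stops_planted < 0L || n_stops_planted > n_codons)
    stop("n_stops_planted must be in [0, n_codons]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  codons <- sample(names(usage), n_codons, replace = TRUE, prob = usage)
  if (n_stops_planted > 0L) {
    pos <- sample.int(n_codons, n_stops_planted)
    codons[pos] <- sample(c("TAA", "TAG", "TGA"), n_stops_planted,
                          replace = TRUE)
  }
  coding_sequence(paste(c(codons, "TAA"), collapse = ""), id = id)
}

#' Generate a congruent host/virus tree pair with planted host switches
#'
#' Simulates an ultrametric host tree under a pure-birth (Yule) process,
#' copies its topology as the virus tree (branch lengths rescaled from Myr
#' to amino-acid substitutions/site by a clock rate), and then applies
#' \code{n_switches} subtree-prune-regraft (SPR) moves to single virus tips,
#' each move constrained to change the rooted topology. Tip associations
#' remain the natural one-to-one host/virus pairing, so every executed move
#' plants one host switch whose identity is recorded in the truth ledger.
#'
#' @param n_tips Number of tips (\code{>= 2}).
#' @param n_switches Number of planted host switches
#'   (\code{0 <= n_switches <= n_tips - 1}); requires \code{n_tips >= 4}
#'   when positive, since smaller rooted trees admit no topology-changing
#'   single-tip move.
#' @param birth Yule birth rate per lineage per Myr (default 0.05, giving
#'   mammal-like depths of tens of Myr for tens of tips).
#' @param clock_rate Virus substitutions/site per Myr used to scale virus
#'   branch lengths (default 0.007, a foamy-virus-like protein clock).
#' @param seed Optional integer seed.
#' @return A list with \code{vtree}, \code{htree} (\code{phylo}),
#'   \code{assoc} (a [tip_association()]), \code{ages} (a [node_ages()]
#'   table for the host tree), and \code{truth} (data frame of moved virus
#'   tips).
#' @export
make_cophylo_pair <- function(n_tips, n_switches = 0L, birth = 0.05,
                              clock_rate = 0.007, seed = NULL) {
  n_tips <- as.integer(n_tips)
  n_switches <- as.integer(n_switches)
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (n_switches < 0L || n_switches > n_tips - 1L)
    stop("n_switches must be in [0, n_tips - 1]", call. = FALSE)
  if (n_switches > 0L && n_tips < 4L)
    stop("planted switches need n_tips >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  htree <- ape::rphylo(n_tips, birth = birth, death = 0)
  htree$tip.label <- paste0("H", seq_len(n_tips))
  vtree <- htree
  vtree$tip.label <- paste0("V", seq_len(n_tips))
  vtree$edge.length <- vtree$edge.length * clock_rate
  moved <- character(0)
  for (s in seq_len(n_switches)) {
    candidates <- setdiff(vtree$tip.label, moved)
    done <- FALSE
    for (attempt in seq_len(200L)) {
      tip <- sample(candidates, 1L)
      cand <- spr_move_tip(vtree, tip)
      if (!is.null(cand) &&
          !isTRUE(ape::all.equal.phylo(cand, vtree,
                                       use.edge.length = FALSE))) {
        vtree <- cand
        moved <- c(moved, tip)
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not place requested switch ", s, call. = FALSE)
  }
  assoc <- tip_association(paste0("V", seq_len(n_tips)),
                           paste0("H", seq_len(n_tips)))
  list(vtree = vtree, htree = htree, assoc = assoc,
       ages = node_ages_from_tree(htree),
       truth = data.frame(moved_tip = moved, stringsAsFactors = FALSE))
}

# One random SPR move of a single tip: prune `tip`, regraft onto a uniformly
# chosen edge other than those adjacent to its original position. Returns
# NULL if the pruned tree admits no valid target.
spr_move_tip <- function(tree, tip) {
  tip_idx <- match(tip, tree$tip.label)
  par <- parent_vec(tree)
  old_parent <- par[tip_idx]
  pruned <- ape::drop.tip(tree, tip)
  if (is.null(pruned) || length(pruned$tip.label) < 2L) return(NULL)
  n_edge <- nrow(pruned$edge)
  targets <- sample.int(n_edge)
  for (e in targets) {
    child <- pruned$edge[e, 2L]
    el <- pruned$edge.length[e]
    out <- tryCatch(
      phytools::bind.tip(pruned, tip, edge.length = el / 2,
                         where = child, position = el / 2),
      error = function(err) NULL)
    if (!is.null(out)) return(out)
  }
  NULL
}

#' Generate synthetic codivergence regression pairs
#'
#' Draws predictor values (host durations, Myr) uniformly on
#' \code{x_range}, sets responses (virus branch lengths) to
#' \code{intercept + slope * x} plus Gaussian noise, and appends planted
#' gross outliers verbatim. The truth of which rows are outliers is carried
#' in the output.
#'
#' @param n Number of regular (in-line) pairs.
#' @param slope,intercept Generating line; slope in subs/site per Myr.
#' @param noise_sd Gaussian noise standard deviation on the response.
#' @param outliers Optional data frame or list with elements/columns
#'   \code{x} and \code{y}: planted outlier coordinates.
#' @param x_range Range of host durations (default \code{c(1, 100)} Myr).
#' @param seed Optional integer seed.
#' @return A data frame of class \code{branch_pairs} with columns
#'   \code{virus_branch}, \code{host_branch}, \code{virus_branch_length},
#'   \code{host_duration}, and \code{is_outlier_truth}.
#' @export
make_regression_pairs <- function(n, slope, intercept = 0, noise_sd = 0,
                                  outliers = NULL, x_range = c(1, 100),
                                  seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- stats::runif(n, x_range[1L], x_range[2L])
  y <- intercept + slope * x + stats::rnorm(n, 0, noise_sd)
  lab <- sprintf("pair_%02d", seq_len(n))
  truth <- rep(FALSE, n)
  if (!is.null(outliers)) {
    ox <- as.numeric(outliers$x)
    oy <- as.numeric(outliers$y)
    stopifnot(length(ox) == length(oy))
    x <- c(x, ox)
    y <- c(y, oy)
    lab <- c(lab, sprintf("outlier_%02d", seq_along(ox)))
    truth <- c(truth, rep(TRUE, length(ox)))
  }
  res <- data.frame(virus_branch = lab, host_branch = lab,
                    virus_branch_length = y, host_duration = x,
                    is_outlier_truth = truth, stringsAsFactors = FALSE)
  class(res) <- c("branch_pairs", "data.frame")
  res
}
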