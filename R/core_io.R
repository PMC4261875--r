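#' Construct a coding sequence
#'
#' A \code{coding_sequence} is an in-frame nucleotide sequence together with
#' the bookkeeping needed to interpret it codon-by-codon: a frame offset
#' (bases skipped before the first codon) and a flag controlling whether the
#' terminal codon of the framed span is excluded from codon counts.
#' Excluding the terminal codon is the convention used when censusing
#' in-frame stop codons in a decayed proviral reading frame, where the last
#' codon may be the authentic stop of the ancestral gene rather than a
#' post-integration mutation.
#'
#' Gap symbols (\code{-}) are stripped before framing. Codons containing any
#' symbol outside \code{A,C,G,T} are excluded from all counts, numerator and
#' denominator alike; a trailing partial codon is ignored.
#'
#' @param bases Character scalar over the alphabet \code{A,C,G,T,N,-}
#'   (lowercase accepted, stored uppercase).
#' @param id Sequence identifier.
#' @param frame_offset Non-negative integer, bases to skip before the first
#'   codon (default 0).
#' @param exclude_terminal Logical; drop the final codon of the framed span
#'   from counts (default \code{TRUE}).
#' @return An object of class \code{coding_sequence}.
#' @seealso [census_stop_codons()], [codon_view()]
#' @export
coding_sequence <- function(bases, id = "seq", frame_offset = 0L,
                            exclude_terminal = TRUE) {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  bad <- setdiff(unique(strsplit(bases, "")[[1]]), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L)
    stop("invalid symbols in sequence '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L)
    stop("frame_offset must be a non-negative integer", call. = FALSE)
  structure(
    list(id = as.character(id), bases = bases,
         frame_offset = frame_offset,
         exclude_terminal = isTRUE(exclude_terminal)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d bases, frame offset %d, terminal codon %s\n",
              x$id, nchar(x$bases), x$frame_offset,
              if (x$exclude_terminal) "excluded" else "counted"))
  invisible(x)
}

#' Codon-wise view of a coding sequence
#'
#' Applies the framing rules of [coding_sequence()]: strips gaps, skips
#' \code{frame_offset} bases, splits the remainder into consecutive triplets,
#' drops a trailing partial codon and, when \code{exclude_terminal} is set,
#' the final complete codon. Codons containing non-ACGT symbols are returned
#' but flagged uncountable.
#'
#' @param seq A [coding_sequence()].
#' @return A data frame with columns \code{index} (1-based codon index in the
#'   framed span), \code{codon}, and \code{countable} (logical).
#' @export
codon_view <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"))
  s <- gsub("-", "", seq$bases, fixed = TRUE)
  if (seq$frame_offset > 0L) {
    if (seq$frame_offset >= nchar(s)) s <- "" else s <- substring(s, seq$frame_offset + 1L)
  }
  n_cod <- nchar(s) %/% 3L
  if (seq$exclude_terminal) n_cod <- n_cod - 1L
  if (n_cod < 1L)
    return(data.frame(index = integer(0), codon = character(0),
                      countable = logical(0)))
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  data.frame(index = seq_len(n_cod), codon = codons,
             countable = !grepl("[^ACGT]", codons))
}

#' Read a FASTA file of coding sequences
#'
#' @param path Path to a FASTA file.
#' @param frame_offset,exclude_terminal Framing applied uniformly to every
#'   record; see [coding_sequence()].
#' @return A list of [coding_sequence()] objects, in file order, sequences
#'   uppercased.
#' @export
read_fasta <- function(path, frame_offset = 0L, exclude_terminal = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1L], " of ", path, call. = FALSE)
  out <- lapply(seq_along(set), function(i)
    coding_sequence(as.character(set[[i]]), id = ids[i],
                    frame_offset = frame_offset,
                    exclude_terminal = exclude_terminal))
  out
}

#' Write coding sequences to FASTA
#'
#' @param seqs A [coding_sequence()] or list thereof.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "coding_sequence")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1), "coding_sequence")))
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "bases"))
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Plain Newick with optional branch lengths; quoted labels are supported.
#' The returned object is an \pkg{ape} \code{phylo}.
#'
#' @param path Path to a single-tree Newick file.
#' @return A rooted \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in '", path, "'", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single tree in '", path, "', found ", length(tr),
           call. = FALSE)
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in '", path, "': ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  tr
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written with enough digits for a lossless round trip
#' (10 significant digits).
#'
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a virus-host tip association table
#'
#' Two-column tab-separated table with columns \code{virus_tip} and
#' \code{host_tip} (a header row is detected and accepted). The table must
#' describe a bijection: no label may appear twice on either side.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class \code{tip_association} with columns
#'   \code{virus_tip} and \code{host_tip}.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) != 2L)
    stop("association table must have exactly 2 tab-separated columns, found ",
         ncol(raw), call. = FALSE)
  if (nrow(raw) > 0L && identical(unname(tolower(unlist(raw[1L, ]))),
                                  c("virus_tip", "host_tip")))
    raw <- raw[-1L, , drop = FALSE]
  tip_association(raw[[1L]], raw[[2L]])
}

#' Construct a tip association (bijection)
#'
#' @param virus_tip,host_tip Character vectors of equal length.
#' @return A data frame of class \code{tip_association}.
#' @export
tip_association <- function(virus_tip, host_tip) {
  virus_tip <- as.character(virus_tip)
  host_tip <- as.character(host_tip)
  stopifnot(length(virus_tip) == length(host_tip))
  if (length(virus_tip) == 0L) stop("empty association table", call. = FALSE)
  dup_v <- unique(virus_tip[duplicated(virus_tip)])
  dup_h <- unique(host_tip[duplicated(host_tip)])
  if (length(dup_v) || length(dup_h))
    stop("association table is not a bijection; duplicated labels: ",
         paste(c(dup_v, dup_h), collapse = ", "), call. = FALSE)
  structure(data.frame(virus_tip = virus_tip, host_tip = host_tip,
                       stringsAsFactors = FALSE),
            class = c("tip_association", "data.frame"))
}

#' Write a tip association table
#' @param assoc A [tip_association()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "tip_association"))
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Check that trees and associations are mutually consistent
#'
#' Verifies that the association bijection covers exactly the tip sets of the
#' virus and host trees. Called by the reconciliation machinery; exported so
#' pipelines can validate inputs up front.
#'
#' @param vtree,htree Rooted \code{phylo} trees.
#' @param assoc A [tip_association()].
#' @return \code{TRUE}, invisibly, or an error naming the offending labels.
#' @export
validate_tip_consistency <- function(vtree, htree, assoc) {
  stopifnot(inherits(vtree, "phylo"), inherits(htree, "phylo"),
            inherits(assoc, "tip_association"))
  miss_v <- setdiff(vtree$tip.label, assoc$virus_tip)
  extra_v <- setdiff(assoc$virus_tip, vtree$tip.label)
  miss_h <- setdiff(htree$tip.label, assoc$host_tip)
  extra_h <- setdiff(assoc$host_tip, htree$tip.label)
  if (length(c(miss_v, extra_v, miss_h, extra_h)))
    stop("associations do not match tree tip sets; offending labels: ",
         paste(unique(c(miss_v, extra_v, miss_h, extra_h)), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# ---- host node ages ---------------------------------------------------------

#' Node-age table for a host tree
#'
#' Host clade ages (Myr before present) keyed by clade tip set rather than by
#' node number, so the same table applies to any re-reading of the tree. The
#' key is the clade's sorted tip labels joined by \code{";"}. Tips default to
#' age 0 and need not be listed.
#'
#' @param clades Character vector of clade keys (sorted tip labels joined by
#'   \code{";"}), or a list of character vectors of tip labels.
#' @param ages Numeric vector of ages in Myr, parallel to \code{clades}.
#' @return A data frame of class \code{node_ages} with columns \code{clade}
#'   and \code{age}.
#' @export
node_ages <- function(clades, ages) {
  if (is.list(clades))
    clades <- vapply(clades, function(x) paste(sort(x), collapse = ";"),
                     character(1))
  stopifnot(length(clades) == length(ages), all(is.finite(ages)),
            all(ages >= 0))
  if (anyDuplicated(clades))
    stop("duplicated clade keys in node age table", call. = FALSE)
  structure(data.frame(clade = as.character(clades), age = as.numeric(ages),
                       stringsAsFactors = FALSE),
            class = c("node_ages", "data.frame"))
}

#' Derive node ages from an ultrametric host tree
#'
#' @param htree An ultrametric, rooted \code{phylo} with branch lengths in
#'   Myr.
#' @return A [node_ages()] table with one row per internal node.
#' @export
node_ages_from_tree <- function(htree) {
  stopifnot(inherits(htree, "phylo"))
  if (!ape::is.ultrametric(htree, tol = 1e-6))
    stop("host tree is not ultrametric; supply ages explicitly", call. = FALSE)
  bt <- ape::branching.times(htree)
  ntip <- length(htree$tip.label)
  keys <- vapply(as.integer(names(bt)), function(nd) {
    tips <- htree$tip.label[descendant_tips(htree, nd)]
    paste(sort(tips), collapse = ";")
  }, character(1))
  ages <- node_ages(keys, as.numeric(bt))
  check_age_table(htree, ages)
  ages
}

#' Read a node-age TSV (clade key, age)
#' @param path Path to a two-column TSV: semicolon-joined sorted clade tips,
#'   age in Myr.
#' @return A [node_ages()] table.
#' @export
read_node_ages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("node age table needs columns clade, age",
                           call. = FALSE)
  node_ages(raw[[1L]], as.numeric(raw[[2L]]))
}

#' Write a node-age table
#' @param ages A [node_ages()] table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_node_ages <- function(ages, path) {
  stopifnot(inherits(ages, "node_ages"))
  utils::write.table(ages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Age of one host node under a node_ages table; tips default to 0.
host_node_age <- function(htree, node, ages) {
  ntip <- length(htree$tip.label)
  if (node <= ntip) {
    key <- htree$tip.label[node]
  } else {
    key <- paste(sort(htree$tip.label[descendant_tips(htree, node)]),
                 collapse = ";")
  }
  hit <- match(key, ages$clade)
  if (is.na(hit)) {
    if (node <= ntip) return(0)
    stop("no age entry for host clade {", key, "}", call. = FALSE)
  }
  ages$age[hit]
}

# Validate parent > child ordering of an age table against a tree.
check_age_table <- function(htree, ages) {
  ntip <- length(htree$tip.label)
  nnode <- htree$Nnode
  a <- vapply((ntip + 1L):(ntip + nnode), host_node_age, numeric(1),
              htree = htree, ages = ages)
  for (e in seq_len(nrow(htree$edge))) {
    p <- htree$edge[e, 1L]; ch <- htree$edge[e, 2L]
    age_p <- a[p - ntip]
    age_c <- if (ch <= ntip) host_node_age(htree, ch, ages) else a[ch - ntip]
    if (age_p <= age_c)
      stop("node age table violates parent > child at clade aged ", age_p,
           call. = FALSE)
  }
  invisible(TRUE)
}

# ---- small tree utilities shared across modules -----------------------------

# Tip indices (1..ntip) descending from `node` in a phylo tree.
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, nd) else stack <- c(stack, kids[[nd]])
  }
  sort(out)
}

# List mapping each node index to its children (empty for tips).
children_list <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(n_all)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  kids
}

# Parent vector (0 for the root).
parent_vec <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  par <- integer(n_all)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# Node indices in postorder (children before parents).
postorder_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  unique(c(tree$edge[, 2L], tree$edge[, 1L]))
}
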