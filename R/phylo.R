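# Neighbor-joining phylogeny of the protein family, bootstrap support,
# and seeded subfamily assignment.

#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA file.
#' @return Named character vector of equal-length gapped rows, class
#'   \code{aa_alignment}.
#' @export
read_protein_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  as_aa_alignment(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Construct an aa_alignment from named gapped strings
#' @param rows Named character vector, all of equal length.
#' @return \code{aa_alignment} object.
#' @export
as_aa_alignment <- function(rows) {
  stopifnot(length(rows) >= 2L, !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  structure(toupper(rows), class = "aa_alignment")
}

#' @noRd
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise protein distances under pairwise gap deletion
#'
#' For each pair only columns where both rows are ungapped are
#' compared. \code{p} is the raw mismatch proportion; \code{poisson}
#' applies the correction \eqn{-\ln(1-p)}. Pairs whose p-distance
#' saturates (p >= 1) get an infinite Poisson distance and are flagged.
#'
#' @param aln \code{aa_alignment} or character matrix (rows = taxa).
#' @param model \code{"poisson"} (default) or \code{"p"}.
#' @return Symmetric distance matrix with a \code{"saturated"} logical
#'   matrix attribute.
#' @export
protein_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- if (is.matrix(aln)) aln else aln_matrix(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ok <- m != "-" & m != "." & m != "?"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns between '", rownames(m)[i],
             "' and '", rownames(m)[j], "'")
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "p") {
        d[i, j] <- d[j, i] <- p
      } else if (p >= 1) {
        d[i, j] <- d[j, i] <- Inf
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via
#' \code{ape::nj}); negative branch lengths are clamped to zero with a
#' message, as is conventional when reporting NJ trees.
#'
#' @param dm Symmetric distance matrix (>= 3 taxa).
#' @return Unrooted \code{phylo} tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(as.matrix(dm)) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(as.matrix(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Columns of the alignment are resampled with replacement
#' \code{n_reps} times; support for each internal edge of the
#' reference tree is the percentage of replicate trees containing the
#' same bipartition, reported as integer percents in
#' \code{tree$node.label}.
#'
#' @param aln \code{aa_alignment}.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed controlling the resampling.
#' @param model Distance model passed to \code{\link{protein_distance}}.
#' @return The reference NJ tree with \code{node.label} set to supports.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  m <- aln_matrix(aln)
  m <- m[order(rownames(m)), , drop = FALSE]  # row-order invariance
  ref <- nj_tree(protein_distance(m, model))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- suppressMessages(nj_tree(protein_distance(m[, cols, drop = FALSE], model)))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.integer(round(100 * counts / n_reps))
  ref
}

#' Assign subfamily labels from seeded clades
#'
#' Each leaf is assigned the label of the smallest proper clade (the
#' whole tree does not count) that contains it together with at least
#' one seed, resolved by majority over the seeds inside that clade
#' (ties broken alphabetically by label). Leaves contained in no
#' seeded proper clade are \code{"unassigned"}. A rooted input tree
#' is used as supplied; an unrooted tree (the usual NJ output) is
#' midpoint-rooted first so that clades are well defined.
#'
#' @param tree \code{phylo} tree.
#' @param seeds Named list: label -> character vector of seed tip ids.
#' @return data.frame with columns \code{id} and \code{subfamily}.
#' @export
assign_subfamilies <- function(tree, seeds) {
  stopifnot(is.list(seeds), length(seeds) >= 1L, !is.null(names(seeds)))
  all_seeds <- unlist(seeds, use.names = FALSE)
  missing <- setdiff(all_seeds, tree$tip.label)
  if (length(missing))
    stop("seed id(s) not in tree: ", paste(missing, collapse = ", "))
  rt <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  ntip <- length(rt$tip.label)
  desc <- phangorn::Descendants(rt, seq_len(ntip + rt$Nnode), type = "tips")
  seed_label <- rep(NA_character_, ntip)
  for (lab in names(seeds))
    seed_label[match(seeds[[lab]], rt$tip.label)] <- lab
  out <- character(ntip)
  for (tip in seq_len(ntip)) {
    if (!is.na(seed_label[tip])) { out[tip] <- seed_label[tip]; next }
    anc <- phangorn::Ancestors(rt, tip, type = "all")
    anc <- anc[-length(anc)]  # the root (whole tree) is not a clade
    label <- "unassigned"
    for (node in anc) {
      tips <- desc[[node]]
      labs <- seed_label[tips]
      labs <- labs[!is.na(labs)]
      if (length(labs)) {
        tab <- sort(table(labs), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        label <- sort(best)[1L]
        break
      }
    }
    out[tip] <- label
  }
  data.frame(id = rt$tip.label, subfamily = out, stringsAsFactors = FALSE)
}

#' Write a tree with integer support labels as Newick
#' @param tree \code{phylo} with optional \code{node.label} supports.
#' @param path Output file.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
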