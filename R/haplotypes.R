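# Haplotype collapsing and per-group tabulation, shared-haplotype
# detection between populations, and the ITS1 fragment-length species
# diagnostic.

# Coerce sequence input (DNAStringSet or named character) to a named
# uppercase character vector, checking id uniqueness.
.asSequences <- function(seqs) {
  if (inherits(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs)) {
    out <- seqs
  } else {
    stopInput("sequences must be a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stopInput("every sequence needs an id (names attribute)")
  if (anyDuplicated(names(out)))
    stopInput("duplicate sequence ids: %s",
              paste(unique(names(out)[duplicated(names(out))]),
                    collapse = ", "))
  toupper(out)
}

# Identity is exact string equality after uppercasing. IUPAC ambiguity
# codes are NOT expanded (an N mismatching an A makes distinct
# haplotypes); `strict` warns when ambiguity codes are present so the
# conservative behaviour is visible.
.checkAmbiguity <- function(seqs, strict) {
  if (!strict) return(invisible())
  amb <- names(seqs)[grepl("[^ACGT-]", seqs)]
  if (length(amb))
    warning("sequences with IUPAC ambiguity codes (treated as literal ",
            "characters, not expanded): ", paste(amb, collapse = ", "),
            call. = FALSE)
  invisible()
}

#' Collapse aligned sequences into haplotypes
#'
#' A haplotype is an equivalence class of identical uppercase residue
#' strings; gap characters, if present, are treated as ordinary
#' characters. Haplotypes are numbered deterministically by first
#' occurrence.
#'
#' @param seqs a \code{Biostrings::DNAStringSet} or named character
#'   vector of equal-length aligned sequences.
#' @param strict warn when ambiguity codes are present (default TRUE).
#' @return named list mapping each haplotype string to the ids carrying
#'   it, ordered by first occurrence.
#' @examples
#' collapseHaplotypes(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
#' @export
collapseHaplotypes <- function(seqs, strict = TRUE) {
  seqs <- .asSequences(seqs)
  if (!length(seqs)) stopInput("no sequences to collapse")
  w <- nchar(seqs)
  if (length(unique(w)) > 1) {
    bad <- names(seqs)[w != w[1]]
    stopInput("unequal sequence lengths (alignment required): %s",
              paste(bad, collapse = ", "))
  }
  .checkAmbiguity(seqs, strict)
  split(names(seqs), factor(seqs, levels = unique(seqs)))
}

#' Per-group haplotype table
#'
#' Collapses sequences within each group (species x locality) and
#' tabulates sequence and haplotype counts per group.
#'
#' @param seqs sequences as in \code{\link{collapseHaplotypes}}.
#' @param groups group label per sequence: a named character vector
#'   (id -> group) or a two-column data.frame (id, group).
#' @param strict warn on ambiguity codes.
#' @return a \linkS4class{HaplotypeTable}.
#' @examples
#' seqs <- c(a1 = "ACGT", a2 = "ACGT", b1 = "ACCT")
#' haplotypeTable(seqs, c(a1 = "popA", a2 = "popA", b1 = "popB"))
#' @export
haplotypeTable <- function(seqs, groups, strict = TRUE) {
  seqs <- .asSequences(seqs)
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[2]]),
                       as.character(groups[[1]]))
  }
  missing <- setdiff(names(seqs), names(groups))
  if (length(missing))
    stopInput("no group label for ids: %s",
              paste(missing, collapse = ", "))
  g <- groups[names(seqs)]
  members <- lapply(split(names(seqs), g[names(seqs)]), function(ids) {
    collapseHaplotypes(seqs[ids], strict = strict)
  })
  empty <- setdiff(unique(groups), names(members))
  if (length(empty))
    stopInput("empty group(s): %s", paste(empty, collapse = ", "))
  tab <- data.frame(
    group = names(members),
    nSequences = vapply(members, function(m) sum(lengths(m)), 0L),
    nHaplotypes = lengths(members),
    row.names = NULL, stringsAsFactors = FALSE
  )
  new("HaplotypeTable", table = tab, members = members)
}

#' Haplotypes shared between two groups
#'
#' The intersection of the two groups' haplotype string sets — e.g. to
#' ask whether island and continental populations share any
#' mitochondrial haplotype.
#'
#' @param table a \linkS4class{HaplotypeTable} (or a second one via
#'   \code{tableB}).
#' @param groupA,groupB group names.
#' @param tableB optional second table (different dataset, same locus);
#'   defaults to \code{table}.
#' @return character vector of shared haplotype sequence strings.
#' @export
sharedHaplotypes <- function(table, groupA, groupB, tableB = table) {
  a <- table@members[[groupA]]
  b <- tableB@members[[groupB]]
  if (is.null(a)) stopInput("unknown group: %s", groupA)
  if (is.null(b)) stopInput("unknown group: %s", groupB)
  la <- unique(nchar(names(a))); lb <- unique(nchar(names(b)))
  if (length(la) == 1 && length(lb) == 1 && la != lb)
    stopInput("groups come from different alignment lengths (%d vs %d)",
              la, lb)
  intersect(names(a), names(b))
}

#' Construct a fragment-length species classifier
#'
#' @param lengths integer fragment lengths in bp.
#' @param labels species label per length.
#' @param tolerance matching tolerance in bp (default 0). Entries whose
#'   lengths collide within the tolerance are flagged with a warning at
#'   construction.
#' @return a \linkS4class{LengthClassifier}.
#' @export
lengthClassifier <- function(lengths, labels, tolerance = 0L) {
  obj <- new("LengthClassifier", lengths = as.integer(lengths),
             labels = labels, tolerance = as.integer(tolerance))
  if (length(lengths) > 1) {
    d <- abs(outer(obj@lengths, obj@lengths, "-"))
    collide <- d <= 2 * obj@tolerance & upper.tri(d)
    if (any(collide))
      warning("classifier entries indistinguishable within tolerance: ",
              paste(apply(which(collide, arr.ind = TRUE), 1, function(ij)
                sprintf("%d/%d bp", obj@lengths[ij[1]],
                        obj@lengths[ij[2]])), collapse = ", "),
              call. = FALSE)
  }
  obj
}

#' The ITS1 length diagnostic for Indian Ocean black flies
#'
#' Ships the published diagnostic: 82 bp = \emph{S. triplex}, 110 bp =
#' \emph{S. ruficorne}, 111 bp = \emph{Simulium} sp. 1 (Seychelles),
#' 116 bp = \emph{S. borbonense}, with tolerance 0. Note that the
#' 110/111 bp pair is indistinguishable on an agarose gel; sequence-level
#' sizing is required to separate them.
#'
#' @param quiet suppress the 110/111 note (default FALSE).
#' @return a \linkS4class{LengthClassifier}.
#' @export
its1Classifier <- function(quiet = FALSE) {
  if (!quiet)
    message("ITS1 classifier: 110 bp (S. ruficorne) and 111 bp ",
            "(Simulium sp. 1) are indistinguishable on agarose gels")
  lengthClassifier(c(82L, 110L, 111L, 116L),
                   c("S. triplex", "S. ruficorne", "Simulium sp. 1",
                     "S. borbonense"),
                   tolerance = 0L)
}

#' Classify a fragment length
#'
#' Exact-match (within tolerance) lookup of an amplicon length. No
#' match returns \code{"unknown"}; two or more entries within tolerance
#' return \code{"ambiguous\{...\}"} listing the candidates.
#'
#' @param length positive integer fragment length in bp (vectorised).
#' @param classifier a \linkS4class{LengthClassifier}.
#' @return character vector of species labels / "unknown" / "ambiguous".
#' @examples
#' classifyByLength(82, its1Classifier(quiet = TRUE))
#' @export
classifyByLength <- function(length, classifier) {
  if (any(length <= 0)) stopInput("fragment lengths must be positive")
  vapply(length, function(L) {
    hit <- which(abs(classifier@lengths - L) <= classifier@tolerance)
    if (!length(hit)) return("unknown")
    if (length(hit) == 1) return(classifier@labels[hit])
    paste0("ambiguous{", paste(classifier@labels[hit], collapse = ", "),
           "}")
  }, "")
}

#' Parse group labels from sequence id suffixes
#'
#' Ids such as \code{"GY018_borb"} carry the group in a suffix; the
#' default pattern captures the text after the last underscore.
#'
#' @param ids character vector of sequence ids.
#' @param pattern a regex with one capture group (default
#'   \code{"_([A-Za-z0-9.]+)$"}).
#' @return named character vector (id -> group).
#' @export
parseGroupsFromIds <- function(ids, pattern = "_([A-Za-z0-9.]+)$") {
  m <- regmatches(ids, regexec(pattern, ids))
  bad <- ids[lengths(m) < 2]
  if (length(bad))
    stopInput("ids without a parseable group suffix: %s",
              paste(bad, collapse = ", "))
  setNames(vapply(m, `[`, "", 2), ids)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; alignment
#' (equal lengths) is checked downstream by the collapsing functions.
#'
#' @param path FASTA file path.
#' @return a \code{DNAStringSet}.
#' @export
readAlignedFasta <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  Biostrings::readDNAStringSet(path)
}
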