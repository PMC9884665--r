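# Bovine rhodopsin (348 aa) -- the standard numbering reference for opsin
# residue positions (chromophore-binding Lys296; counterion sites 94/113/181).
.bovine_rhodopsin <- paste0(
  "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLY",
  "VTVQHKKLRTPLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLG",
  "GEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIP",
  "EGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQES",
  "ATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQGSDFGPIFMTIPAFFAKTSAV",
  "YNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA"
)

#' Bovine rhodopsin reference sequence
#'
#' Returns the 348-residue bovine rhodopsin amino-acid sequence embedded in
#' the package. All residue numbers reported by [counterion_report()] refer
#' to positions in this sequence ("bovine rhodopsin numbering").
#'
#' @return A single character string of 348 one-letter residue codes.
#' @export
bovine_rhodopsin <- function() .bovine_rhodopsin

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"

.check_aa <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1L]]
  bad <- !chars %in% strsplit(.aa_alphabet, "")[[1L]]
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s contains non-amino-acid character '%s' at position %d",
                 what, chars[i], i), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment (end gaps penalized) with a substitution
#' matrix and affine gap penalties, as implemented by
#' \code{Biostrings::pairwiseAlignment}. A gap of length L costs
#' \code{gap_open + L * gap_extend}. Deterministic: identical inputs always
#' produce identical alignments.
#'
#' @param seq1,seq2 Amino-acid strings (20 standard residues plus X).
#' @param matrix Substitution matrix name (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 1).
#' @return List with \code{score}, \code{aligned1}, \code{aligned2} (gapped
#'   strings of equal length).
#' @export
align_global <- function(seq1, seq2, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  seq1 <- .check_aa(seq1, "seq1")
  seq2 <- .check_aa(seq2, "seq2")
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(score = Biostrings::score(pa),
       aligned1 = as.character(Biostrings::alignedPattern(pa)),
       aligned2 = as.character(Biostrings::alignedSubject(pa)))
}

#' Align an opsin query to bovine rhodopsin numbering
#'
#' Globally aligns a query opsin sequence to the embedded bovine rhodopsin
#' reference and builds the residue-number map that lets positions in the
#' query be addressed in bovine rhodopsin numbering (e.g. "position 296").
#'
#' @param query Amino-acid string, length >= 100.
#' @param query_id Label for the query (default \code{"query"}).
#' @inheritParams align_global
#' @return An object of class \code{numbered_alignment}: list with
#'   \code{query_id}, \code{aligned_query}, \code{aligned_reference} and
#'   \code{position_map} (integer vector indexed by bovine residue number
#'   1..348; NA where the reference residue aligns to a gap in the query).
#' @export
align_to_bovine <- function(query, query_id = "query", matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 1) {
  query <- .check_aa(query, "query")
  if (nchar(query) < 100L) {
    stop("query must be at least 100 residues to be aligned reliably",
         call. = FALSE)
  }
  al <- align_global(query, .bovine_rhodopsin, matrix = matrix,
                     gap_open = gap_open, gap_extend = gap_extend)
  q <- strsplit(al$aligned1, "")[[1L]]
  r <- strsplit(al$aligned2, "")[[1L]]
  pos_map <- rep(NA_integer_, nchar(.bovine_rhodopsin))
  qi <- 0L; ri <- 0L
  for (k in seq_along(r)) {
    if (q[k] != "-") qi <- qi + 1L
    if (r[k] != "-") {
      ri <- ri + 1L
      if (q[k] != "-") pos_map[ri] <- qi
    }
  }
  structure(
    list(query_id = query_id, query = query,
         aligned_query = al$aligned1, aligned_reference = al$aligned2,
         score = al$score, position_map = pos_map),
    class = "numbered_alignment"
  )
}

#' @export
print.numbered_alignment <- function(x, ...) {
  cat(sprintf("alignment of %s to bovine rhodopsin: score %.1f, %d/%d reference positions mapped\n",
              x$query_id, x$score, sum(!is.na(x$position_map)),
              length(x$position_map)))
  invisible(x)
}

#' Residue of the query at a bovine rhodopsin position
#'
#' @param alignment A \code{numbered_alignment}.
#' @param position Bovine rhodopsin residue number (1-based).
#' @return One-letter residue code, or \code{"gap"} if the position aligns
#'   to a gap in the query.
#' @export
residue_at <- function(alignment, position) {
  stopifnot(inherits(alignment, "numbered_alignment"),
            position >= 1, position <= length(alignment$position_map))
  qpos <- alignment$position_map[position]
  if (is.na(qpos)) "gap" else substr(alignment$query, qpos, qpos)
}

#' Chromophore-binding and counterion site report
#'
#' Checks the two sequence-level diagnostics of a functional visible-light
#' opsin in bovine rhodopsin numbering: the retinal-binding lysine at
#' position 296, and the presence of a negatively charged residue (Asp or
#' Glu; no pKa modelling) at the known counterion positions 94, 113 and 181.
#' An opsin lacking D/E at all three counterion sites cannot stabilize the
#' protonated retinylidene Schiff base at those positions, which suggests UV
#' sensitivity or a non-canonical counterion.
#'
#' @param alignment A \code{numbered_alignment} from [align_to_bovine()].
#' @return An object of class \code{counterion_report}: list with
#'   \code{query_id}, \code{lys296_present}, \code{lys296_gap},
#'   \code{residues} (named character vector for sites 94, 113, 181) and
#'   \code{negatively_charged_sites} (integer subset of c(94, 113, 181)).
#' @export
counterion_report <- function(alignment) {
  stopifnot(inherits(alignment, "numbered_alignment"))
  sites <- c(94L, 113L, 181L)
  res <- vapply(sites, function(p) residue_at(alignment, p), character(1))
  names(res) <- as.character(sites)
  r296 <- residue_at(alignment, 296L)
  structure(
    list(query_id = alignment$query_id,
         lys296_present = identical(r296, "K"),
         lys296_gap = identical(r296, "gap"),
         residue_296 = r296,
         residues = res,
         negatively_charged_sites = sites[res %in% c("D", "E")]),
    class = "counterion_report"
  )
}

#' @export
print.counterion_report <- function(x, ...) {
  cat(sprintf("%s: Lys296 %s; sites 94/113/181 = %s; negative at {%s}\n",
              x$query_id,
              if (x$lys296_present) "present"
              else if (x$lys296_gap) "absent (gap)" else
                sprintf("absent (%s)", x$residue_296),
              paste(x$residues, collapse = "/"),
              paste(x$negatively_charged_sites, collapse = ", ")))
  invisible(x)
}

#' Counterion report for every record of a FASTA file
#'
#' @param path Path to a multi-record amino-acid FASTA file.
#' @return A data.frame with one row per record: \code{query_id},
#'   \code{lys296}, \code{res94}, \code{res113}, \code{res181},
#'   \code{negative_sites} (comma-separated).
#' @export
seqcheck_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- lapply(seq_along(aa), function(i) {
    rep_ <- counterion_report(
      align_to_bovine(as.character(aa[[i]]), query_id = names(aa)[i]))
    data.frame(query_id = rep_$query_id,
               lys296 = rep_$lys296_present,
               res94 = rep_$residues[["94"]],
               res113 = rep_$residues[["113"]],
               res181 = rep_$residues[["181"]],
               negative_sites = paste(rep_$negatively_charged_sites,
                                      collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
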