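#' @include AllClasses.R
NULL

CANONICAL_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' The standard genetic code as a codon -> residue map
#'
#' Returns the 64-entry standard code (DNA alphabet). Stop codons carry the
#' token `"*"`; suppression overrides are applied downstream, never here.
#'
#' @return named character vector of length 64 (names are codons).
#' @examples
#' code <- standardGeneticCode()
#' code[c("TGT", "TAG")]
#' @export
standardGeneticCode <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
}

#' Expand an IUPAC degenerate codon into its concrete codons
#'
#' `"NNK"` expands to 32 codons (covering all 20 canonical residues plus the
#' TAG stop), `"NNN"` to 64, `"NNB"` to 48.
#'
#' @param scheme a 3-letter IUPAC degenerate codon, e.g. `"NNK"`.
#' @return character vector of concrete A/C/G/T codons.
#' @examples
#' length(expandDegenerateCodon("NNK"))
#' @export
expandDegenerateCodon <- function(scheme) {
  stopifnot(is.character(scheme), length(scheme) == 1L)
  if (nchar(scheme) != 3L) {
    stop("codon scheme must have exactly 3 letters, got '", scheme, "'")
  }
  letters3 <- strsplit(toupper(scheme), "")[[1]]
  bad <- setdiff(letters3, names(IUPAC_DNA))
  if (length(bad)) {
    stop("non-IUPAC letter(s) in codon scheme: ", paste(bad, collapse = ", "))
  }
  g <- expand.grid(IUPAC_DNA[[letters3[3]]], IUPAC_DNA[[letters3[2]]],
                   IUPAC_DNA[[letters3[1]]], stringsAsFactors = FALSE)
  sort(paste0(g[[3]], g[[2]], g[[1]]))
}

#' Serialize / parse residue-token sequences
#'
#' Peptides with non-canonical residues are serialized as comma-free strings
#' with multi-character tokens wrapped in parentheses, e.g.
#' `"CWRVFIWGQGP(AcrK)"`. `parsePeptide` inverts the serialization.
#'
#' @param tokens character vector of residue tokens (one element per residue).
#' @param x serialized peptide string.
#' @return `formatPeptide`: a single string; `parsePeptide`: a character
#'   vector of tokens.
#' @examples
#' formatPeptide(c("C", "D", "AcrK"))
#' parsePeptide("CD(AcrK)")
#' @export
formatPeptide <- function(tokens) {
  multi <- nchar(tokens) > 1L
  tokens[multi] <- paste0("(", tokens[multi], ")")
  paste(tokens, collapse = "")
}

#' @rdname formatPeptide
#' @export
parsePeptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  out <- regmatches(x, gregexpr("\\(([^)]+)\\)|.", x))[[1]]
  sub("^\\(([^)]+)\\)$", "\\1", out)
}

# codon -> token lookup under a suppression map; unsuppressed stops become NA
.codonTokenMap <- function(code = standardGeneticCode(), suppression = character()) {
  map <- code
  if (length(suppression)) map[names(suppression)] <- suppression
  map[map == "*"] <- NA_character_
  map
}

#' Translate DNA with stop-codon suppression
#'
#' Each codon is looked up first in the suppression map, then in the base
#' code; any unsuppressed stop rejects the sequence. Returns the residue
#' tokens in order (1-based positions) or a rejection with a reason.
#'
#' @param dna a nucleotide string (A/C/G/T), length divisible by 3.
#' @param code base genetic code, see [standardGeneticCode()].
#' @param suppression named character vector of codon -> token overrides
#'   (e.g. `c(TAG = "AcrK")`); may be empty.
#' @return a list with elements `status` (`"ok"` or one of `"frame"`,
#'   `"ambiguous"`, `"stop"`), and on success `tokens` (character vector)
#'   plus `peptide` (serialized string).
#' @examples
#' translateWithSuppression("TGTGATTAG", suppression = c(TAG = "AcrK"))
#' translateWithSuppression("TGTTAA", suppression = c(TAG = "AcrK"))$status
#' @export
translateWithSuppression <- function(dna, code = standardGeneticCode(),
                                     suppression = character()) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L) {
    return(list(status = "frame", tokens = NULL, peptide = NA_character_))
  }
  if (grepl("[^ACGT]", dna)) {
    return(list(status = "ambiguous", tokens = NULL, peptide = NA_character_))
  }
  nc <- nchar(dna) %/% 3L
  codons <- substring(dna, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  map <- .codonTokenMap(code, suppression)
  tokens <- unname(map[codons])
  if (anyNA(tokens)) {
    return(list(status = "stop", tokens = NULL, peptide = NA_character_))
  }
  list(status = "ok", tokens = tokens, peptide = formatPeptide(tokens))
}

# Vectorized translator for equal-length DNA windows (the ingest/simulator
# fast path). Returns list(peptide = chr (NA on rejection), status = chr).
.translateMany <- function(dna, suppression = character()) {
  n <- length(dna)
  if (n == 0L) return(list(peptide = character(), status = character()))
  status <- rep("ok", n)
  width <- nchar(dna)
  frame <- width %% 3L != 0L
  amb <- !frame & grepl("[^ACGT]", dna)
  status[frame] <- "frame"
  status[amb] <- "ambiguous"
  ok <- !frame & !amb
  peptide <- rep(NA_character_, n)
  if (any(ok)) {
    map <- .codonTokenMap(suppression = suppression)
    # wrap multi-char tokens once, at the map level
    disp <- map
    multi <- !is.na(disp) & nchar(disp) > 1L
    disp[multi] <- paste0("(", disp[multi], ")")
    idx <- which(ok)
    for (L in unique(width[idx])) {
      sel <- idx[width[idx] == L]
      k <- L %/% 3L
      starts <- 3L * seq_len(k) - 2L
      cod <- matrix("", nrow = length(sel), ncol = k)
      for (j in seq_len(k)) {
        cod[, j] <- substr(dna[sel], starts[j], starts[j] + 2L)
      }
      tok <- matrix(disp[cod], nrow = length(sel))
      hasStop <- rowSums(is.na(tok)) > 0L
      status[sel[hasStop]] <- "stop"
      keep <- !hasStop
      if (any(keep)) {
        peptide[sel[keep]] <- do.call(paste0, asplit(tok[keep, , drop = FALSE], 2L))
      }
    }
  }
  list(peptide = peptide, status = status)
}
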