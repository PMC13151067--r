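#' @include AllClasses.R genetic-code.R
NULL

# simulator-default constant flanks (the real amplicon primers are a user
# concern; these stand in for them in simulated data)
FLANK5_DEFAULT <- "GCCCAGCCGGCCATGGCTTC"
FLANK3_DEFAULT <- "GGTGGAGGCGGTTCAGGCGG"

#' Construct a LibrarySchema
#'
#' @param name schema identifier.
#' @param pattern data.frame with columns `type` (`"fixed"`/`"random"`),
#'   `token` (fixed residue token or `NA`), `scheme` (fixed codon or IUPAC
#'   degenerate codon).
#' @param suppression named character vector of codon -> ncAA-token overrides.
#' @param flank5,flank3 constant DNA flanking the variable region.
#' @return a validated [LibrarySchema-class] object.
#' @examples
#' librarySchema("mini",
#'   data.frame(type = c("fixed", "random"), token = c("C", NA),
#'              scheme = c("TGT", "NNK")))
#' @export
librarySchema <- function(name, pattern, suppression = character(),
                          flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT) {
  new("LibrarySchema", name = name, pattern = pattern,
      suppression = suppression, flank5 = flank5, flank3 = flank3)
}

#' Built-in library schemas
#'
#' `schemaCX10AcrK()` is a 10-mer amber-suppressed macrocycle library: a fixed
#' N-terminal Cys, ten NNK-randomized positions, and a fixed TAG codon decoded
#' to the non-canonical residue AcrK (N-epsilon-acryloyl-lysine), whose
#' acryloyl group closes a thioether macrocycle with the Cys. Displayed
#' peptides look like `"CWRVFIWGQGP(AcrK)"`.
#'
#' `schemaCX12C()` is a 12-mer chemically cyclized library: twelve
#' NNK-randomized residues flanked by an N-terminal and an internal (here,
#' C-terminal of the variable region) cysteine, cyclized post-expression by a
#' bifunctional linker. No suppression: clones drawing a TAG at a randomized
#' position are translation-rejected.
#'
#' @param flank5,flank3 constant flanking DNA (simulator defaults).
#' @return a [LibrarySchema-class].
#' @examples
#' schemaCX12C()
#' @export
schemaCX10AcrK <- function(flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT) {
  pattern <- data.frame(
    type = c("fixed", rep("random", 10L), "fixed"),
    token = c("C", rep(NA_character_, 10L), "AcrK"),
    scheme = c("TGT", rep("NNK", 10L), "TAG"),
    stringsAsFactors = FALSE
  )
  librarySchema("CX10AcrK", pattern, suppression = c(TAG = "AcrK"),
                flank5 = flank5, flank3 = flank3)
}

#' @rdname schemaCX10AcrK
#' @export
schemaCX12C <- function(flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT) {
  pattern <- data.frame(
    type = c("fixed", rep("random", 12L), "fixed"),
    token = c("C", rep(NA_character_, 12L), "C"),
    scheme = c("TGT", rep("NNK", 12L), "TGT"),
    stringsAsFactors = FALSE
  )
  librarySchema("CX12C", pattern, flank5 = flank5, flank3 = flank3)
}

# tokens producible at each pattern position (suppression applied, stops out)
.allowedTokens <- function(schema) {
  p <- scaffoldPattern(schema)
  map <- .codonTokenMap(suppression = suppressionMap(schema))
  lapply(seq_len(nrow(p)), function(i) {
    if (p$type[i] == "fixed") return(p$token[i])
    tok <- map[expandDegenerateCodon(p$scheme[i])]
    unique(tok[!is.na(tok)])
  })
}

#' Test whether a peptide matches a library scaffold
#'
#' True iff the peptide has the schema's length, every fixed position carries
#' its required token, and every randomized position carries a token its codon
#' scheme can produce under the suppression map. Total function: any input
#' yields `TRUE` or `FALSE`, never an error.
#'
#' @param peptide serialized peptide string (see [formatPeptide()]) or a
#'   character vector of residue tokens.
#' @param schema a [LibrarySchema-class].
#' @return logical scalar.
#' @examples
#' matchesScaffold("CDSWFFWDEHTDDC", schemaCX12C())
#' matchesScaffold("ADSWFFWDEHTDDC", schemaCX12C())
#' @export
matchesScaffold <- function(peptide, schema) {
  tokens <- if (length(peptide) == 1L) parsePeptide(peptide) else peptide
  allowed <- .allowedTokens(schema)
  if (length(tokens) != length(allowed)) return(FALSE)
  all(vapply(seq_along(tokens),
             function(i) tokens[i] %in% allowed[[i]], logical(1)))
}

# vectorized scaffold check over serialized peptide strings
.matchesScaffoldMany <- function(peptides, schema) {
  allowed <- .allowedTokens(schema)
  k <- length(allowed)
  toks <- regmatches(peptides, gregexpr("\\(([^)]+)\\)|.", peptides))
  vapply(toks, function(tk) {
    if (length(tk) != k) return(FALSE)
    tk <- sub("^\\(([^)]+)\\)$", "\\1", tk)
    for (i in seq_len(k)) if (!tk[i] %in% allowed[[i]]) return(FALSE)
    TRUE
  }, logical(1))
}

#' Encode a scaffold-valid peptide back into DNA
#'
#' Chooses, per position, a codon consistent with the schema (the fixed codon
#' at fixed positions; a uniformly sampled compatible codon at randomized
#' positions). Translating the result under the schema's suppression map
#' recovers the identical token sequence.
#'
#' @param peptide serialized peptide string or token vector.
#' @param schema a [LibrarySchema-class].
#' @return a DNA string of length `variableRegionLength(schema)`.
#' @export
encodePeptide <- function(peptide, schema) {
  tokens <- if (length(peptide) == 1L) parsePeptide(peptide) else peptide
  p <- scaffoldPattern(schema)
  if (length(tokens) != nrow(p)) {
    stop("peptide length does not match schema '", schemaName(schema), "'")
  }
  map <- .codonTokenMap(suppression = suppressionMap(schema))
  codons <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (p$type[i] == "fixed") {
      codons[i] <- p$scheme[i]
      next
    }
    cands <- expandDegenerateCodon(p$scheme[i])
    cands <- cands[!is.na(map[cands]) & map[cands] == tokens[i]]
    if (!length(cands)) {
      stop("token '", tokens[i], "' at position ", i,
           " is not encodable by scheme ", p$scheme[i])
    }
    codons[i] <- if (length(cands) == 1L) cands else sample(cands, 1L)
  }
  paste(codons, collapse = "")
}

#' Read / write a library schema config
#'
#' Schemas serialize to a small YAML document: `name`, a `pattern` list of
#' `fixed`/`random` position specs, the `suppression` map, and both flanks.
#'
#' @param schema a [LibrarySchema-class].
#' @param path file path.
#' @return `readSchema` returns a [LibrarySchema-class];
#'   `writeSchema` returns `path` invisibly.
#' @export
writeSchema <- function(schema, path) {
  p <- scaffoldPattern(schema)
  spec <- lapply(seq_len(nrow(p)), function(i) {
    if (p$type[i] == "fixed") {
      list(type = "fixed", token = p$token[i], codon = p$scheme[i])
    } else {
      list(type = "random", scheme = p$scheme[i])
    }
  })
  yaml::write_yaml(list(
    name = schemaName(schema),
    pattern = spec,
    suppression = as.list(suppressionMap(schema)),
    flank5 = unname(flanks(schema)["flank5"]),
    flank3 = unname(flanks(schema)["flank3"])
  ), path)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  y <- yaml::read_yaml(path)
  pattern <- do.call(rbind, lapply(y$pattern, function(s) {
    if (identical(s$type, "fixed")) {
      data.frame(type = "fixed", token = s$token, scheme = s$codon,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(type = "random", token = NA_character_, scheme = s$scheme,
                 stringsAsFactors = FALSE)
    }
  }))
  sup <- unlist(y$suppression)
  if (is.null(sup)) sup <- character()
  librarySchema(y$name, pattern, suppression = sup,
                flank5 = y$flank5, flank3 = y$flank3)
}
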