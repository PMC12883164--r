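#' @import methods
#' @importFrom stats median pnorm pt p.adjust aov TukeyHSD lm coef vcov
#'   confint rnorm rbinom rnbinom rlnorm runif rgamma setNames sd var
#'   quantile complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

STOP_CHAR <- "*"

#' Site classes for codon positions
#'
#' Constants naming the three mutually exclusive classes a codon position can
#' take: fourfold degenerate (every substitution is synonymous), strictly
#' nonsynonymous (every substitution changes the residue), or mixed.
#' Fourfold-degenerate positions are the "synonymous site" pool used for
#' synonymous GC content and skew; strictly nonsynonymous positions form the
#' nonsynonymous pool; mixed positions belong to neither.
#'
#' @export
SITE_FOURFOLD <- "fourfold"

#' @rdname SITE_FOURFOLD
#' @export
SITE_NONSYNONYMOUS <- "nonsynonymous"

#' @rdname SITE_FOURFOLD
#' @export
SITE_MIXED <- "mixed"

#' GeneticCode class
#'
#' A codon translation table: the mapping from all 64 DNA codons to amino
#' acids (one-letter IUPAC) or the stop marker \code{"*"}. The default is
#' NCBI translation table 11 (bacterial, archaeal and plant plastid), whose
#' sense/stop assignments match the standard code; other tables can be
#' selected by id or loaded from a plain-text file.
#'
#' @slot tableId integer NCBI translation table identifier.
#' @slot codonToAa named character vector of length 64 mapping DNA codons
#'   (names, alphabet ACGT) to one-letter residues or \code{"*"} for stop.
#'
#' @seealso [geneticCode()], [translateCodon()], [classifySite()]
#' @export
setClass("GeneticCode",
  representation(tableId = "integer", codonToAa = "character"))

ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"),
  function(ab, c) paste0(substr(ab, 1, 1), substr(ab, 2, 2), c)))
ALL_CODONS <- sort(ALL_CODONS)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonToAa) != 64L)
    msg <- c(msg, "codonToAa must have exactly 64 entries")
  if (!setequal(names(object@codonToAa), ALL_CODONS))
    msg <- c(msg, "codonToAa names must be the 64 ACGT codons")
  aa <- object@codonToAa
  bad <- !(aa %in% c(LETTERS, STOP_CHAR)) | nchar(aa) != 1L
  if (any(bad))
    msg <- c(msg, "codonToAa values must be one-letter residues or '*'")
  if (!any(aa == STOP_CHAR))
    msg <- c(msg, "code must contain at least one stop codon")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneticCode", function(object) {
  n_stop <- sum(object@codonToAa == STOP_CHAR)
  cat("GeneticCode (NCBI table ", object@tableId, "): ",
      64L - n_stop, " sense codons, ", n_stop, " stop codons, ",
      length(unique(object@codonToAa[object@codonToAa != STOP_CHAR])),
      " amino acids\n", sep = "")
})

#' Construct a genetic code by NCBI table id
#'
#' @param table_id integer NCBI translation table identifier (default 11,
#'   bacterial).
#' @return A [GeneticCode-class] object.
#' @examples
#' code <- geneticCode()
#' translateCodon("GAA", code)
#' @export
geneticCode <- function(table_id = 11L) {
  tbl <- Biostrings::getGeneticCode(as.character(table_id))
  attributes(tbl) <- list(names = names(tbl))
  new("GeneticCode", tableId = as.integer(table_id),
      codonToAa = tbl[ALL_CODONS])
}

#' Load a genetic code from a plain-text table
#'
#' Reads a two-column whitespace/tab-separated file (codon, residue) with 64
#' rows; \code{"*"} marks stops. The packaged default for table 11 lives at
#' \code{system.file("extdata", "genetic_code_table11.txt",
#' package = "codonTraits")}.
#'
#' @param path file path.
#' @param table_id integer id to record on the returned object.
#' @return A [GeneticCode-class].
#' @export
loadGeneticCode <- function(path, table_id = NA_integer_) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("genetic code file must have two columns: codon, residue")
  codons <- toupper(trimws(tab[[1]]))
  aa <- trimws(tab[[2]])
  if (anyDuplicated(codons))
    stop("duplicate codon entries in genetic code file")
  map <- setNames(aa, codons)
  new("GeneticCode", tableId = as.integer(table_id), codonToAa = map[ALL_CODONS])
}

#' Translate codons to residues
#'
#' @param codon character vector of 3-mers over ACGT (RNA `U` is accepted and
#'   converted to `T`).
#' @param code a [GeneticCode-class].
#' @return character vector of one-letter residues, \code{"*"} for stops, and
#'   \code{NA} for codons containing non-ACGT characters (the caller decides
#'   whether to skip or fail).
#' @export
translateCodon <- function(codon, code = geneticCode()) {
  codon <- chartr("u", "U", toupper(codon))
  codon <- chartr("U", "T", codon)
  out <- unname(code@codonToAa[codon])
  out
}

#' Sense and stop codons of a code
#'
#' @param code a [GeneticCode-class].
#' @return character vector of codons.
#' @export
senseCodons <- function(code = geneticCode())
  names(code@codonToAa)[code@codonToAa != STOP_CHAR]

#' @rdname senseCodons
#' @export
stopCodons <- function(code = geneticCode())
  names(code@codonToAa)[code@codonToAa == STOP_CHAR]

#' Synonymous codon families
#'
#' `synonymousFamilies()` returns every family; `synonymousFamily()` the
#' family of one residue. A family is the set of codons encoding one amino
#' acid; its size `r_a` (1 to 6 under the standard bacterial code) enters the
#' MILC short-sequence correction and the ENC' degeneracy classes. The
#' families partition the sense codons; stops have no family.
#'
#' @param code a [GeneticCode-class].
#' @param residue one-letter amino acid symbol.
#' @return For `synonymousFamily()`, a list with elements `amino_acid`,
#'   `codons` (sorted character vector) and `r_a` (family size). For
#'   `synonymousFamilies()`, a named list of such lists, one per amino acid.
#' @examples
#' synonymousFamily("E")$codons  # GAA, GAG
#' @export
synonymousFamilies <- function(code = geneticCode()) {
  sense <- code@codonToAa[code@codonToAa != STOP_CHAR]
  split_codons <- split(names(sense), sense)
  lapply(split_codons, function(cs)
    list(amino_acid = code@codonToAa[[cs[1]]],
         codons = sort(cs), r_a = length(cs)))
}

#' @rdname synonymousFamilies
#' @export
synonymousFamily <- function(residue, code = geneticCode()) {
  if (identical(residue, STOP_CHAR))
    stop("stop marker has no synonymous family")
  fams <- synonymousFamilies(code)
  if (is.null(fams[[residue]]))
    stop("unknown residue: ", residue)
  fams[[residue]]
}

#' Classify a codon position by substitution effect
#'
#' A position is fourfold degenerate when all three single-nucleotide
#' substitutions at that position leave the encoded residue unchanged,
#' strictly nonsynonymous when all three change it, and mixed otherwise.
#' Mixed positions contribute to whole-gene GC content but to neither the
#' synonymous nor the nonsynonymous site pool.
#'
#' @param codon a sense codon (3-mer over ACGT).
#' @param position integer in 1..3.
#' @param code a [GeneticCode-class].
#' @return One of [SITE_FOURFOLD], [SITE_NONSYNONYMOUS], [SITE_MIXED].
#' @examples
#' classifySite("GCA", 3)  # fourfold: GCN all encode Ala
#' @export
classifySite <- function(codon, position, code = geneticCode()) {
  codon <- chartr("U", "T", toupper(codon))
  aa <- translateCodon(codon, code)
  if (is.na(aa)) stop("ambiguous codon: ", codon)
  if (aa == STOP_CHAR) stop("stop codon has no site class: ", codon)
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  nts <- c("A", "C", "G", "T")
  ref_nt <- substr(codon, position, position)
  alts <- setdiff(nts, ref_nt)
  alt_aa <- vapply(alts, function(nt) {
    mut <- codon
    substr(mut, position, position) <- nt
    code@codonToAa[[mut]]
  }, character(1))
  same <- alt_aa == aa
  if (all(same)) SITE_FOURFOLD
  else if (!any(same)) SITE_NONSYNONYMOUS
  else SITE_MIXED
}

# cached per-code lookup: 64 codons x 3 positions -> site class (NA for stops
# and, under classifySite's definition, computed once per table id)
.site_class_cache <- new.env(parent = emptyenv())

siteClassTable <- function(code = geneticCode()) {
  key <- paste0("t", code@tableId, "_",
                paste(code@codonToAa, collapse = ""))
  hit <- .site_class_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- matrix(NA_character_, nrow = 64L, ncol = 3L,
                dimnames = list(ALL_CODONS, NULL))
  for (cd in senseCodons(code))
    for (p in 1:3)
      tab[cd, p] <- classifySite(cd, p, code)
  .site_class_cache[[key]] <- tab
  tab
}
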