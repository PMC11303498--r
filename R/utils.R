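# Internal helpers shared across modules.

AUTOSOMES <- as.character(1:22)
CANONICAL_CHROMS <- c(AUTOSOMES, "X", "Y")

GT_CLASSES <- c("hom_ref", "het", "hom_alt", "missing")
PARENT_STATUS <- c("carries", "does_not_carry", "unknown")
ORIGIN_CLASSES <- c("maternal_only", "paternal_only", "biparental", "neither",
                    "unknown", "not_called")
SETUPS <- c("single", "duo_mother", "duo_father", "trio")

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix so "chr1" and "1" compare equal, and maps
#' "MT"/"M" to "MT". Non-canonical contigs (decoys, alts) are returned as-is;
#' callers decide whether to keep them.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x == "M"] <- "MT"
  x
}

# Order chromosomes 1..22, X, Y, then everything else alphabetically.
chrom_order <- function(x) {
  idx <- match(x, CANONICAL_CHROMS)
  idx[is.na(idx)] <- length(CANONICAL_CHROMS) + rank(x[is.na(idx)])
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# Deterministic 31-bit sub-seed for per-family RNG streams: family output must
# not depend on cohort ordering, and derived seeds must stay below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}
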