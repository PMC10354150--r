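#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' The six collapsed base-substitution types
#'
#' Substitutions are reported in unordered base-pair notation, so a C>T
#' change and its complementary G>A change on the other strand belong to the
#' same class, `"C:G>T:A"`. The six classes cover all 12 directed
#' substitutions.
#'
#' @format Character vector of length 6.
#' @export
deam_types <- c("C:G>T:A", "A:T>G:C", "A:T>T:A", "G:C>T:A", "A:T>C:G", "G:C>C:G")

# directed substitution -> collapsed pair notation
.pair_lookup <- c(
  "C>T" = "C:G>T:A", "G>A" = "C:G>T:A",
  "A>G" = "A:T>G:C", "T>C" = "A:T>G:C",
  "A>T" = "A:T>T:A", "T>A" = "A:T>T:A",
  "G>T" = "G:C>T:A", "C>A" = "G:C>T:A",
  "A>C" = "A:T>C:G", "T>G" = "A:T>C:G",
  "G>C" = "G:C>C:G", "C>G" = "G:C>C:G"
)

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; operates on plain upper-case ACGTN strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TCG")
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Collapse a directed substitution to unordered pair notation
#'
#' @param ref,obs Reference and observed base (character vectors, recycled).
#' @return Character vector of collapsed type labels (see [deam_types]).
#' @export
#' @examples
#' collapse_type("G", "A") # same class as C>T
collapse_type <- function(ref, obs) {
  out <- unname(.pair_lookup[paste0(ref, ">", obs)])
  if (anyNA(out)) {
    abort("`ref` and `obs` must be distinct bases in A/C/G/T.",
          class = "deamscan_invalid_argument")
  }
  out
}

#' Collapse a trinucleotide context onto its canonical strand
#'
#' A context and its reverse complement are counted as one; the canonical
#' representative is the triplet whose focal (middle) base is C or A, so a
#' G>A event seen at 5'CGA3' on the top strand collapses to 5'TCG3'.
#'
#' @param triplet Character vector of 3-base contexts.
#' @return Character vector of canonical triplets (focal base C or A).
#' @export
#' @examples
#' collapse_context(c("CGA", "TGT", "TCG"))
collapse_context <- function(triplet) {
  flip <- substr(triplet, 2, 2) %in% c("G", "T")
  triplet[flip] <- revcomp(triplet[flip])
  triplet
}

# all 16 collapsed contexts for a given focal base ("C" or "A")
.all_contexts <- function(focal) {
  as.vector(t(outer(DNA_BASES, DNA_BASES, function(x, y) paste0(x, focal, y))))
}

# Phred+33 helpers ------------------------------------------------------------

phred_to_int <- function(q) utf8ToInt(q) - 33L

int_to_phred <- function(x) intToUtf8(pmin(x, 93L) + 33L)

# Evaluate with a temporarily seeded RNG; NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# argument checks -------------------------------------------------------------

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
          class = "deamscan_invalid_argument")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")),
          class = "deamscan_malformed_input")
  }
  invisible(df)
}
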