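# Internal helpers shared across modules.

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards. All exported stochastic functions route through this so
# no global state leaks between stages.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible sub-seed for a named stage from a master seed,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

iupac_table <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Normalise an IUPAC consensus string
#'
#' Accepts plain IUPAC strings plus two shorthands common in the fungal TF
#' literature: fixed-length gaps written `N8` or `-N8-` (e.g. `CGG-N8-MGG`)
#' and two-base alternatives written `(C/A)`.
#'
#' @param consensus character scalar.
#' @return Uppercase IUPAC string with gaps expanded to runs of `N`.
#' @export
normalize_consensus <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  x <- toupper(gsub("-", "", consensus))
  # (C/A) style alternatives -> IUPAC code
  while (grepl("\\(([ACGT])/([ACGT])\\)", x)) {
    m <- regmatches(x, regexpr("\\(([ACGT])/([ACGT])\\)", x))[[1]]
    bases <- sort(strsplit(gsub("[()/]", "", m), "")[[1]])
    code <- names(iupac_table)[vapply(iupac_table, function(s) {
      identical(sort(strsplit(s, "")[[1]]), bases)
    }, logical(1))][1]
    x <- sub("\\(([ACGT])/([ACGT])\\)", code, x)
  }
  # N8 style gaps -> NNNNNNNN
  while (grepl("N[0-9]+", x)) {
    m <- regmatches(x, regexpr("N[0-9]+", x))[[1]]
    n <- as.integer(sub("N", "", m))
    x <- sub("N[0-9]+", strrep("N", n), x)
  }
  bad <- setdiff(strsplit(x, "")[[1]], names(iupac_table))
  if (length(bad) > 0) {
    abort(paste0("consensus contains non-IUPAC characters: ", paste(bad, collapse = ", ")))
  }
  x
}

iupac_to_regex <- function(consensus) {
  chars <- strsplit(normalize_consensus(consensus), "")[[1]]
  paste0(vapply(chars, function(ch) {
    opts <- iupac_table[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw one concrete realisation of an IUPAC consensus.
sample_consensus_sequence <- function(consensus) {
  chars <- strsplit(normalize_consensus(consensus), "")[[1]]
  paste0(vapply(chars, function(ch) {
    opts <- strsplit(iupac_table[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# Half-open interval overlap width between [s1,e1) and [s2,e2).
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
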