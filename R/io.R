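# Sequence input and seeded random sequences.

#' Read a FASTA file into sequence records
#'
#' Parses a (multi-record) FASTA file and applies an out-of-alphabet symbol
#' policy: `"reject"` errors on the first invalid symbol, `"strip"` removes
#' invalid symbols, and `"skip-split"` splits each record at runs of invalid
#' symbols into separate records (ids suffixed `/1`, `/2`, ...), which
#' preserves true adjacency within each piece.
#'
#' @param path FASTA file.
#' @param policy out-of-alphabet symbol policy.
#' @param alphabet characters considered valid (default DNA, `ACGT`;
#'   matching is case-insensitive and sequences are upper-cased).
#' @return a data.frame with columns `id` and `seq`; empty (with a warning)
#'   for an empty file.
#' @export
read_fasta <- function(path, policy = c("reject", "skip-split", "strip"),
                       alphabet = "ACGT") {
  policy <- match.arg(policy)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(data.frame(id = character(0), seq = character(0)))
  }
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)  # keep the token before the first whitespace
  seqs <- toupper(as.character(set))
  ok_re <- paste0("[^", alphabet, "]")
  out_id <- character(0)
  out_seq <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (!grepl(ok_re, s)) {
      out_id <- c(out_id, ids[[i]]); out_seq <- c(out_seq, s)
      next
    }
    if (policy == "reject") {
      bad <- regmatches(s, regexpr(ok_re, s))
      stop(sprintf("record '%s' contains symbol '%s' outside alphabet %s (policy = reject)",
                   ids[[i]], bad, alphabet))
    }
    if (policy == "strip") {
      out_id <- c(out_id, ids[[i]])
      out_seq <- c(out_seq, gsub(ok_re, "", s))
      next
    }
    pieces <- strsplit(gsub(paste0(ok_re, "+"), "\n", s), "\n")[[1]]
    pieces <- pieces[nzchar(pieces)]
    out_id <- c(out_id, paste0(ids[[i]], "/", seq_along(pieces)))
    out_seq <- c(out_seq, pieces)
  }
  keep <- nzchar(out_seq)
  if (!all(keep)) warning("dropping records that are empty after applying the symbol policy")
  data.frame(id = out_id[keep], seq = out_seq[keep])
}

# run code with a fixed RNG seed, restoring the caller's RNG state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Seeded i.i.d. uniform random sequence
#'
#' @param sigma alphabet size.
#' @param length sequence length (>= 0).
#' @param seed RNG seed; the same seed always yields the same sequence, and
#'   the caller's RNG state is left untouched.
#' @return integer vector of symbols in `[sigma]`.
#' @export
random_sequence <- function(sigma, length, seed) {
  stopifnot(sigma >= 1, length >= 0)
  if (length == 0) return(integer(0))
  .with_seed(seed, sample.int(sigma, length, replace = TRUE) - 1L)
}
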