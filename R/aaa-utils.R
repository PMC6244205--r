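#' @importFrom stats as.dist cor cutree hclust phyper rlnorm rnorm runif
#'   sd setNames wilcox.test
#' @importFrom utils combn head read.delim write.table
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA20, "X", "*")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# residues conventionally counted hydrophobic for CXC polarity
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "M", "F", "W", "C", "P", "G")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of their seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' @param dna character string over A,C,G,T,N (case-insensitive).
#' @return reverse-complemented upper-case string.
#' @export
#' @examples
#' revcomp("ATGC")  # "GCAT"
revcomp <- function(dna) {
  dna <- toupper(dna)
  vapply(dna, function(s) {
    paste(rev(seq_chars(chartr("ACGTN", "TGCAN", s))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' A sequence record
#'
#' Lightweight container for a single named sequence. DNA is restricted to
#' A,C,G,T,N and proteins to the 20 standard residues plus X and `*`;
#' residues are upper-cased on ingest.
#'
#' @param id sequence identifier.
#' @param residues sequence string.
#' @param alphabet `"dna"` or `"protein"`.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty")
  allowed <- if (alphabet == "dna") DNA_ALPHABET else AA_ALPHABET
  bad <- setdiff(unique(seq_chars(residues)), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s residue(s) in '%s': %s",
                 alphabet, id, paste(bad, collapse = ", ")))
  }
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "seq_record")
}

# Accept either a seq_record or a bare string for sequence arguments.
as_residues <- function(x, alphabet = NULL) {
  if (inherits(x, "seq_record")) {
    if (!is.null(alphabet) && x$alphabet != alphabet)
      stop(sprintf("expected a %s sequence, got %s", alphabet, x$alphabet))
    x$residues
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

#' Read a multi-record FASTA file
#'
#' @param path file path.
#' @param alphabet `"dna"` or `"protein"`.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

# codon -> amino acid, standard genetic code (table 1), stops as '*'
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Translate a coding DNA string
#'
#' Standard genetic code; stop codons render `*`; any codon containing N
#' renders `X`; a trailing partial codon is dropped.
#'
#' @param dna DNA string (or `seq_record`).
#' @return protein string.
#' @export
translate_dna <- function(dna) {
  s <- as_residues(dna, "dna")
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}
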