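# Shared sequence primitives: alphabet checks, k-mer seeding, seeded pairwise
# alignment, bacterial translation, FASTA I/O.

DNA_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
PROTEIN_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

# Alignment scoring scheme. Only relative ordering matters for the
# thresholded decisions downstream; these are conventional defaults.
DNA_MATCH <- 2L
DNA_MISMATCH <- -3L
DNA_GAP_OPEN <- 5L    # penalty (positive); a gap of length L costs open + L*ext
DNA_GAP_EXT <- 2L
PROT_GAP_OPEN <- 11L
PROT_GAP_EXT <- 1L
SEED_K_DNA <- 15L
SEED_K_PROTEIN <- 5L
BAND_WIDTH <- 32L

validate_sequence <- function(seq, alphabet = c("dna", "protein"), what = "sequence") {
  alphabet <- match.arg(alphabet)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stopf("%s must be a non-empty character scalar", what)
  }
  seq <- toupper(seq)
  allowed <- if (alphabet == "dna") DNA_CHARS else PROTEIN_CHARS
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    stopf("invalid %s character(s) in %s: %s", alphabet, what,
          paste(sQuote(bad), collapse = ", "))
  }
  seq
}

dna_substitution_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- matrix(DNA_MISMATCH, length(DNA_CHARS), length(DNA_CHARS),
                  dimnames = list(DNA_CHARS, DNA_CHARS))
      diag(m)[1:4] <- DNA_MATCH  # only unambiguous self-matches score as match
      cache <<- m
    }
    cache
  }
})

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Integer codes of all k-mers of `seq` (A=0,C=1,G=2,T=3); windows containing
# ambiguity codes are NA. Requires 4^k < 2^31 (k <= 15).
kmer_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  lut <- rep(NA_real_, 128L)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("T")] <- 3
  v <- lut[utf8ToInt(seq)]
  nw <- n - k + 1L
  code <- numeric(nw)
  for (j in seq_len(k)) code <- code * 4 + v[j:(nw + j - 1L)]
  code
}

# Character k-mers of a protein sequence (k small, sequences short).
protein_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Seeded pairwise alignment
#'
#' Finds the highest-scoring alignment between two sequences by shared
#' k-mer seeding followed by dynamic-programming extension in a window
#' around the best seed diagonal. Returns `NULL` when the sequences share
#' no exact k-mer (k = 15 for DNA, 5 for protein), which is how downstream
#' modules model "no detectable homology".
#'
#' @param query,subject Character scalars over the declared alphabet
#'   (IUPAC ambiguity codes allowed for DNA).
#' @param mode `"local"` (Smith-Waterman style, both sequences local) or
#'   `"glocal"` (query global, subject local; used for fragment mapping).
#' @param alphabet `"dna"` or `"protein"`. DNA scores 2/-3 with gap open/extend
#'   5/2; protein uses BLOSUM62 with gap 11/1.
#' @param band Half-width of the subject window around the best seed
#'   diagonal (default 32).
#' @param subject_codes Optional precomputed k-mer codes of the subject
#'   (`kmer_codes(subject, 15)` for DNA), for callers that align many
#'   queries against one subject.
#'
#' @return A list of class `"skincat_alignment"` with `query_id`, `subject_id`
#'   (filled by callers), 1-based inclusive `query_start/query_end/
#'   subject_start/subject_end`, `identity` (matches over aligned columns,
#'   gaps counted as mismatches), `query_coverage`, and `score`; or `NULL`
#'   if no seed is shared.
#' @export
align_pair <- function(query, subject, mode = c("local", "glocal"),
                       alphabet = c("dna", "protein"), band = BAND_WIDTH,
                       subject_codes = NULL) {
  mode <- match.arg(mode)
  alphabet <- match.arg(alphabet)
  query <- validate_sequence(query, alphabet, "query")
  subject <- validate_sequence(subject, alphabet, "subject")

  k <- if (alphabet == "dna") SEED_K_DNA else SEED_K_PROTEIN
  if (alphabet == "dna") {
    qk <- kmer_codes(query, k)
    sk <- if (is.null(subject_codes)) kmer_codes(subject, k) else subject_codes
  } else {
    qk <- protein_kmers(query, k)
    sk <- if (is.null(subject_codes)) protein_kmers(subject, k) else subject_codes
  }
  hit <- match(qk, sk)                  # first subject position per query k-mer
  seeded <- which(!is.na(hit) & !is.na(qk))
  if (length(seeded) == 0L) return(NULL)

  # Most-supported diagonal (subject pos - query pos) anchors the window.
  # Periodic sequences tie many diagonals; among ties, prefer the diagonal
  # whose band window is largest so repeats are not truncated at a window
  # edge.
  diags <- hit[seeded] - seeded
  qlen <- nchar(query)
  slen <- nchar(subject)
  tab <- table(diags)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1L) {
    wsize <- pmin(slen, top + qlen + band) - pmax(1L, top + 1L - band) + 1L
    top <- top[order(-wsize, abs(top), top)]
  }
  best_diag <- top[1L]
  ws <- max(1L, best_diag + 1L - band)
  we <- min(slen, best_diag + qlen + band)
  window <- substr(subject, ws, we)

  sm <- if (alphabet == "dna") dna_substitution_matrix() else blosum62_matrix()
  go <- if (alphabet == "dna") DNA_GAP_OPEN else PROT_GAP_OPEN
  ge <- if (alphabet == "dna") DNA_GAP_EXT else PROT_GAP_EXT
  type <- if (mode == "local") "local" else "global-local"
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = window, type = type,
    substitutionMatrix = sm, gapOpening = go, gapExtension = ge
  )

  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ncol_aln <- length(pat)
  # Equal ambiguity characters (N-N, X-X) are not evidence of identity,
  # mirroring the substitution matrices where only unambiguous characters
  # score as a match.
  unamb <- if (alphabet == "dna") c("A", "C", "G", "T")
           else setdiff(PROTEIN_CHARS, "X")
  nmatch <- sum(pat == sub & pat %in% unamb)
  identity <- nmatch / ncol_aln

  qs <- IRanges::start(Biostrings::pattern(aln))
  qe <- IRanges::end(Biostrings::pattern(aln))
  ss <- IRanges::start(Biostrings::subject(aln)) + ws - 1L
  se <- IRanges::end(Biostrings::subject(aln)) + ws - 1L

  structure(list(
    query_id = NA_character_, subject_id = NA_character_,
    query_start = qs, query_end = qe,
    subject_start = ss, subject_end = se,
    identity = identity,
    query_coverage = (qe - qs + 1L) / qlen,
    n_columns = ncol_aln,
    score = Biostrings::score(aln)
  ), class = "skincat_alignment")
}

#' @export
print.skincat_alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.3f, query %d-%d, subject %d-%d\n",
              x$score, x$identity, x$query_start, x$query_end,
              x$subject_start, x$subject_end))
  invisible(x)
}

#' Translate a coding sequence (bacterial code, table 11)
#'
#' @param cds DNA sequence of the coding region in genome-forward
#'   orientation; length must be a multiple of 3 after strand resolution.
#' @param strand `"+"` or `"-"`; `"-"` reverse-complements before translating.
#' @return Protein sequence as a character scalar; codons containing
#'   ambiguity codes translate to `"X"`, stop codons to `"*"`.
#' @export
translate_cds <- function(cds, strand = "+") {
  cds <- validate_sequence(cds, "dna", "cds")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (nchar(cds) %% 3L != 0L) {
    stopf("cds length %d is not divisible by 3", nchar(cds))
  }
  x <- Biostrings::DNAString(cds)
  if (strand == "-") x <- Biostrings::reverseComplement(x)
  as.character(Biostrings::translate(
    x, genetic.code = Biostrings::getGeneticCode("11"), if.fuzzy.codon = "X"
  ))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a FASTA file
#'
#' @param path File path.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of sequences (upper case).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param alphabet `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
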