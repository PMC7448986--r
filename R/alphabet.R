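# Internal sequence encodings shared by the search and gene-model kernels.
# Protein alphabet: 20 standard residues, B/Z ambiguity codes, X, and '*'
# (stop, retained as a symbol in translated frames). DNA: A,C,G,T,N.

CR_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
CR_AA_X <- 22L    # 0-based index of 'X'
CR_AA_STOP <- 23L # 0-based index of '*'
CR_DNA <- c("A", "C", "G", "T", "N")

cr_encode_aa <- function(x, strict = FALSE) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, CR_AA)
  if (anyNA(idx)) {
    if (strict) {
      bad <- unique(ch[is.na(idx)])
      stop("non-amino-acid symbols in sequence: ", paste(bad, collapse = ", "))
    }
    idx[is.na(idx)] <- CR_AA_X + 1L
  }
  idx - 1L
}

cr_decode_aa <- function(idx) paste(CR_AA[idx + 1L], collapse = "")

cr_encode_dna <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, CR_DNA)
  idx[is.na(idx)] <- 5L # any IUPAC ambiguity handled as N
  idx - 1L
}

# BLOSUM62 over CR_AA with the stop row/column floored at -4 so that
# translated stops score as plain mismatches instead of ending alignments.
cr_submat <- function() {
  if (!is.null(.cr_env$submat)) return(.cr_env$submat)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[CR_AA, CR_AA]
  b["*", ] <- -4
  b[, "*"] <- -4
  storage.mode(b) <- "double"
  .cr_env$submat <- b
  b
}

# 125-entry lookup: codon code b1*25 + b2*5 + b3 (A,C,G,T,N = 0..4) -> 0-based
# CR_AA index; any N-containing codon translates to X.
cr_codon2aa <- function() {
  if (!is.null(.cr_env$codon2aa)) return(.cr_env$codon2aa)
  gc <- Biostrings::GENETIC_CODE
  tab <- rep(CR_AA_X, 125L)
  nts <- c("A", "C", "G", "T")
  for (i in 0:3) for (j in 0:3) for (k in 0:3) {
    codon <- paste0(nts[i + 1], nts[j + 1], nts[k + 1])
    tab[i * 25L + j * 5L + k + 1L] <- match(gc[[codon]], CR_AA) - 1L
  }
  .cr_env$codon2aa <- as.integer(tab)
  .cr_env$codon2aa
}

cr_translate_cds <- function(cds) {
  idx <- cr_encode_dna(cds)
  n <- (length(idx) %/% 3L) * 3L
  if (n == 0L) return("")
  b <- matrix(idx[seq_len(n)], nrow = 3L)
  code <- b[1L, ] * 25L + b[2L, ] * 5L + b[3L, ] + 1L
  paste(CR_AA[cr_codon2aa()[code] + 1L], collapse = "")
}

cr_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run code with a locally-seeded RNG without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
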