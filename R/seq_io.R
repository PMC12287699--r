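# FASTA / MSA input-output, codon <-> amino-acid conversion, and optional
# external aligner adapters. Parsing and writing go through Biostrings; the
# gap-codon handling needed for codon MSAs is done here.

#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a named character vector, uppercasing residues.
#' Labels must be unique and residues restricted to A/C/G/T/N/- (the
#' ambiguity code N is accepted and encoded as all-zero channels
#' downstream).
#'
#' @param path FASTA file.
#' @param msa if `TRUE`, additionally require all rows to have equal length.
#' @param alphabet `"nt"` (default) restricts residues to A/C/G/T/N/-;
#'   `"aa"` admits amino-acid letters (used for aligner intermediates).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, msa = FALSE, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file", call. = FALSE)
  seqs <- toupper(as.character(set))
  # Biostrings keeps full header lines; first token is the label
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels in FASTA", call. = FALSE)
  bad <- if (alphabet == "nt") grepl("[^ACGTN-]", seqs)
         else grepl("[^A-Z*-]", seqs)
  if (any(bad))
    stop("non-IUPAC characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  if (msa && length(unique(nchar(seqs))) != 1)
    stop("rows of unequal length cannot form an MSA", call. = FALSE)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file; residues are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

.split_codons <- function(nt) {
  if (nchar(nt) %% 3 != 0)
    stop("sequence length not divisible by 3", call. = FALSE)
  substring(nt, seq(1, nchar(nt), by = 3), seq(3, nchar(nt), by = 3))
}

#' Translate a codon sequence to amino acids
#'
#' Universal-code translation; the gap codon `---` maps to the gap character
#' `-`. A stop codon before the final position is an error; a terminal stop
#' translates to `*`.
#'
#' @param nt_sequence nucleotide string, length divisible by 3, possibly
#'   gapped in whole codons.
#' @return amino-acid string of length `nchar(nt_sequence) / 3`.
#' @export
#' @examples
#' translate_codons("ATGAAA")      # "MK"
#' translate_codons("ATG---AAA")   # "M-K"
translate_codons <- function(nt_sequence) {
  codons <- .split_codons(toupper(nt_sequence))
  gc_map <- Biostrings::GENETIC_CODE
  aa <- character(length(codons))
  for (i in seq_along(codons)) {
    cd <- codons[i]
    if (cd == "---") { aa[i] <- "-"; next }
    if (grepl("[^ACGT]", cd))
      stop("invalid codon '", cd, "' at codon position ", i, call. = FALSE)
    aa[i] <- gc_map[[cd]]
    if (aa[i] == "*" && i < length(codons))
      stop("internal stop codon at codon position ", i, call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Back-translate an amino-acid alignment to codons
#'
#' Replaces each amino-acid residue of the aligned rows by its source codon
#' from the corresponding unaligned nucleotide sequence, and each amino-acid
#' gap by the gap codon `---` (the operation PAL2NAL performs). Nucleotide
#' content is never altered, only gap codons are inserted.
#'
#' @param aa_msa named character vector of equal-length amino-acid rows.
#' @param nt_sequences named character vector of ungapped nucleotide
#'   sequences; for each taxon `translate_codons(nt)` must equal the
#'   ungapped amino-acid row.
#' @return named character vector: the codon MSA, `L = 3 *` aa length.
#' @export
#' @examples
#' backtranslate_alignment(c(a = "M-K"), c(a = "ATGAAA"))
backtranslate_alignment <- function(aa_msa, nt_sequences) {
  stopifnot(length(unique(nchar(aa_msa))) == 1)
  if (!all(names(aa_msa) %in% names(nt_sequences)))
    stop("missing nucleotide sequence for some aligned taxa", call. = FALSE)
  out <- character(length(aa_msa))
  for (t in seq_along(aa_msa)) {
    taxon <- names(aa_msa)[t]
    aa <- strsplit(aa_msa[[t]], "")[[1]]
    nt <- nt_sequences[[taxon]]
    codons <- .split_codons(nt)
    aa_src <- strsplit(translate_codons(nt), "")[[1]]
    k <- 0L
    row <- character(length(aa))
    for (j in seq_along(aa)) {
      if (aa[j] == "-") { row[j] <- "---"; next }
      k <- k + 1L
      if (k > length(aa_src) || aa_src[k] != aa[j])
        stop(sprintf(
          "translation mismatch for taxon '%s' at aligned residue %d ('%s' vs '%s')",
          taxon, j, aa[j], if (k <= length(aa_src)) aa_src[k] else "?"),
          call. = FALSE)
      row[j] <- codons[k]
    }
    if (k != length(aa_src))
      stop(sprintf("taxon '%s': %d residues unaccounted for after alignment",
                   taxon, length(aa_src) - k), call. = FALSE)
    out[t] <- paste(row, collapse = "")
  }
  names(out) <- names(aa_msa)
  out
}

.aligner_exe <- c(clustalo = "clustalo", mafft = "mafft",
                  "prank-aa" = "prank", "prank-codon" = "prank")

#' Align sequences with an external aligner
#'
#' Thin adapter over optional external executables. Amino-acid tools
#' (`clustalo`, `mafft`, `prank-aa`) are fed translated sequences and the
#' result is back-translated to codons; `prank-codon` aligns nucleotides
#' directly under its codon model. Tool defaults are used; the executed
#' command line is attached to the result as attribute `command`.
#'
#' @param tool one of `"clustalo"`, `"mafft"`, `"prank-aa"`,
#'   `"prank-codon"`.
#' @param sequences named character vector of unaligned coding sequences.
#' @param workdir scratch directory for tool input/output.
#' @return named character vector: the codon MSA.
#' @export
run_external_aligner <- function(tool = c("clustalo", "mafft", "prank-aa",
                                          "prank-codon"),
                                 sequences, workdir = tempfile("aln")) {
  tool <- match.arg(tool)
  exe <- .aligner_exe[[tool]]
  if (Sys.which(exe) == "")
    stop("optional dependency absent: executable '", exe,
         "' not found on PATH", call. = FALSE)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  aa_mode <- tool != "prank-codon"
  input <- if (aa_mode) vapply(sequences, translate_codons, "") else sequences
  in_fa <- file.path(workdir, "input.fasta")
  out_fa <- file.path(workdir, "output.fasta")
  write_fasta(input, in_fa)
  args <- switch(tool,
    clustalo = c("-i", in_fa, "-o", out_fa, "--force"),
    mafft = c("--auto", "--quiet", in_fa),
    "prank-aa" = c(paste0("-d=", in_fa),
                   paste0("-o=", file.path(workdir, "out")), "-once"),
    "prank-codon" = c(paste0("-d=", in_fa), "-codon",
                      paste0("-o=", file.path(workdir, "out")), "-once"))
  if (tool == "mafft") {
    res <- suppressWarnings(system2(exe, args, stdout = out_fa,
                                    stderr = FALSE))
    status <- res
  } else {
    res <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
  }
  if (!is.null(status) && is.numeric(status) && length(status) == 1 &&
      status != 0)
    stop("aligner '", tool, "' failed: ",
         paste(utils::head(res, 20), collapse = "\n"), call. = FALSE)
  if (grepl("^prank", tool)) {
    cand <- Sys.glob(file.path(workdir, "out.best.fas"))
    if (length(cand) == 0) cand <- Sys.glob(file.path(workdir, "out*.fas"))
    if (length(cand) == 0)
      stop("aligner 'prank' produced no output", call. = FALSE)
    out_fa <- cand[1]
  }
  aligned <- read_fasta(out_fa, msa = TRUE,
                        alphabet = if (aa_mode) "aa" else "nt")
  aligned <- aligned[names(sequences)]
  msa <- if (aa_mode) backtranslate_alignment(aligned, sequences)
         else aligned
  attr(msa, "command") <- paste(exe, paste(args, collapse = " "))
  msa
}

#' Strip gap characters from alignment rows
#'
#' @param msa named character vector of gapped rows.
#' @return named character vector of ungapped sequences.
#' @export
strip_gaps <- function(msa) {
  out <- gsub("-", "", msa, fixed = TRUE)
  names(out) <- names(msa)
  out
}
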