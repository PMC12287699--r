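# One-hot tensor encoding of MSAs, batching with zero padding, and a
# versioned streamable record container for encoded datasets.
#
# Channel order is frozen (it indexes saliency maps): reading the bit
# patterns A:00001, C:00010, G:00100, T:01000, -:10000 from the leftmost bit
# to the rightmost, the five channels are gap, T, G, C, A. Padding is
# all-zero and therefore never collides with any character code; the
# ambiguity code N is also encoded all-zero.

.CHANNELS <- c("-", "T", "G", "C", "A")

#' One-hot encode an MSA
#'
#' Converts an `n x L` codon MSA into a binary `n x L x 5` tensor with
#' channels (gap, T, G, C, A). `N` encodes as an all-zero vector.
#'
#' @param msa named character vector of equal-length rows over
#'   A/C/G/T/N/-, `L` divisible by 3.
#' @param label binary gene label (0/1).
#' @param gene_id identifier carried along with the tensor.
#' @return an object of class `encoded_example`: list with `tensor`
#'   (`n x L x 5` 0/1 array), `label`, `gene_id`, `n`, `L`.
#' @export
#' @examples
#' ex <- encode_msa(c(t1 = "ATG", t2 = "A-G"), label = 1)
#' ex$tensor[2, 2, ]  # gap channel hot
encode_msa <- function(msa, label, gene_id = "gene") {
  if (length(unique(nchar(msa))) != 1)
    stop("encoding error: rows of unequal length", call. = FALSE)
  n <- length(msa)
  L <- nchar(msa[[1]])
  if (L %% 3 != 0)
    stop("encoding error: L not divisible by 3", call. = FALSE)
  chars <- matrix(unlist(strsplit(msa, "")), nrow = n, byrow = TRUE)
  bad <- !(chars %in% c(.CHANNELS, "N"))
  if (any(bad))
    stop("encoding error: invalid character(s) ",
         paste(unique(chars[bad]), collapse = " "), call. = FALSE)
  tensor <- array(0, dim = c(n, L, 5))
  for (c in seq_along(.CHANNELS)) {
    hit <- chars == .CHANNELS[c]
    tensor[, , c][hit] <- 1
  }
  structure(list(tensor = tensor, label = as.integer(label),
                 gene_id = gene_id, n = n, L = L),
            class = "encoded_example")
}

#' Decode a one-hot tensor back to an MSA
#'
#' Inverse of [encode_msa()] on its image. All-zero positions decode to `N`
#' (the convention for ambiguity and padding); more than one hot channel at
#' a position is an error.
#'
#' @param tensor binary `n x L x 5` array.
#' @param labels optional row labels (defaults to `t1..tn`).
#' @return named character vector of rows.
#' @export
decode_tensor <- function(tensor, labels = NULL) {
  stopifnot(length(dim(tensor)) == 3, dim(tensor)[3] == 5)
  n <- dim(tensor)[1]; L <- dim(tensor)[2]
  hot <- apply(tensor != 0, c(1, 2), sum)
  if (any(hot > 1))
    stop("decoding error: multiple hot channels at one position",
         call. = FALSE)
  idx <- apply(tensor, c(1, 2), which.max)
  idx[hot == 0] <- 0L
  lookup <- c("N", .CHANNELS)
  rows <- apply(idx, 1, function(r) paste(lookup[r + 1L], collapse = ""))
  names(rows) <- if (is.null(labels)) paste0("t", seq_len(n)) else labels
  rows
}

#' Assemble zero-padded batches of encoded examples
#'
#' Randomly partitions the examples into batches of `batch_size` and stacks
#' each batch into a `B x n x Lmax x 5` array, zero-padding every example on
#' the right to the length of the longest alignment in its batch. With
#' `shuffle_rows`, each example's row order is independently permuted (used
#' to withhold tree-topology information from the classifier).
#'
#' @param examples list of `encoded_example` objects with equal `n`.
#' @param batch_size examples per batch (last batch may be smaller).
#' @param shuffle_rows independently permute each example's rows.
#' @param shuffle randomly permute example order (as done per epoch during
#'   training); set `FALSE` to keep input order.
#' @return list of batches; each batch is a list with `tensor`
#'   (`B x n x Lmax x 5`), `labels`, `lengths` (true L per example), and
#'   `gene_ids`.
#' @export
make_batches <- function(examples, batch_size = 512, shuffle_rows = FALSE,
                         shuffle = TRUE) {
  if (length(examples) == 0)
    stop("empty example set", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  n <- examples[[1]]$n
  if (!all(vapply(examples, `[[`, 0L, "n") == n))
    stop("all examples must have the same number of taxa", call. = FALSE)
  ord <- if (shuffle) sample.int(length(examples)) else seq_along(examples)
  starts <- seq(1, length(ord), by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1, length(ord))]
    B <- length(idx)
    Ls <- vapply(examples[idx], `[[`, 0L, "L")
    Lmax <- max(Ls)
    tensor <- array(0, dim = c(B, n, Lmax, 5))
    for (b in seq_len(B)) {
      ex <- examples[[idx[b]]]
      tb <- ex$tensor
      if (shuffle_rows) tb <- tb[sample.int(n), , , drop = FALSE]
      tensor[b, , seq_len(ex$L), ] <- tb
    }
    list(tensor = tensor,
         labels = vapply(examples[idx], `[[`, 0L, "label"),
         lengths = Ls,
         gene_ids = vapply(examples[idx], `[[`, "", "gene_id"))
  })
}

.REC_MAGIC <- charToRaw("SELCNNR1")
.REC_VERSION <- 1L

#' Write encoded examples to a record file
#'
#' Serializes examples into a versioned, streamable binary container: a
#' fixed header (magic, version, taxon count, record count) followed by
#' length-prefixed records, so readers can stream without loading the whole
#' file.
#'
#' @param examples list of `encoded_example` objects sharing `n`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(examples, path) {
  if (length(examples) == 0) stop("empty example set", call. = FALSE)
  n <- examples[[1]]$n
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.REC_MAGIC, con)
  writeBin(c(.REC_VERSION, n, length(examples)), con, size = 4,
           endian = "little")
  for (ex in examples) {
    id_raw <- charToRaw(ex$gene_id)
    writeBin(c(length(id_raw), ex$label, ex$L), con, size = 4,
             endian = "little")
    writeBin(id_raw, con)
    writeBin(as.raw(ex$tensor), con)
  }
  invisible(path)
}

#' Open a record file for streaming reads
#'
#' Returns an iterator closure; each call yields the next
#' `encoded_example`, or `NULL` after the last record. Memory use is
#' bounded by one record regardless of file size.
#'
#' @param path a [write_records()] file.
#' @return a function of no arguments; it carries attributes `n` and
#'   `count` from the header.
#' @export
record_reader <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = length(.REC_MAGIC))
  if (!identical(magic, .REC_MAGIC)) {
    close(con)
    stop("format error: not a record file", call. = FALSE)
  }
  hdr <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (length(hdr) != 3 || hdr[1] != .REC_VERSION) {
    close(con)
    stop("format error: unsupported record file version", call. = FALSE)
  }
  n <- hdr[2]; count <- hdr[3]
  seen <- 0L
  open_flag <- TRUE
  it <- function() {
    if (!open_flag) return(NULL)
    meta <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    if (length(meta) == 0) {
      close(con); open_flag <<- FALSE
      if (seen != count)
        stop("format error: header count mismatch (", count,
             " declared, ", seen, " found)", call. = FALSE)
      return(NULL)
    }
    if (length(meta) != 3) {
      close(con); open_flag <<- FALSE
      stop("format error: truncated record file", call. = FALSE)
    }
    id_len <- meta[1]; label <- meta[2]; L <- meta[3]
    gene_id <- rawToChar(readBin(con, "raw", n = id_len))
    payload <- readBin(con, "raw", n = n * L * 5)
    if (length(payload) != n * L * 5) {
      close(con); open_flag <<- FALSE
      stop("format error: truncated record file", call. = FALSE)
    }
    seen <<- seen + 1L
    structure(list(tensor = array(as.numeric(payload), dim = c(n, L, 5)),
                   label = label, gene_id = gene_id, n = n, L = L),
              class = "encoded_example")
  }
  attr(it, "n") <- n
  attr(it, "count") <- count
  it
}

#' Read all encoded examples from a record file
#'
#' @param path a [write_records()] file.
#' @return list of `encoded_example` objects.
#' @export
read_records <- function(path) {
  it <- record_reader(path)
  out <- vector("list", attr(it, "count"))
  i <- 0L
  repeat {
    ex <- it()
    if (is.null(ex)) break
    i <- i + 1L
    out[[i]] <- ex
  }
  out[seq_len(i)]
}
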