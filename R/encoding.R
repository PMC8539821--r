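# Sequence encodings: 23-column one-hot matrices and 43-column PSSMs.

# 20 standard residues then the ambiguity symbols B, Z, X. U (selenocysteine)
# maps to C, O (pyrrolysine) to K, J and anything else to X.
.ALPHABET23 <- strsplit("ACDEFGHIKLMNPQRSTVWYBZX", "")[[1]]

#' The 23-letter protein alphabet
#'
#' Column order of the one-hot encoding: the 20 standard amino acids in
#' alphabetical one-letter order, then the ambiguity letters B, Z and X.
#'
#' @return Character vector of length 23.
#' @export
protein_alphabet <- function() .ALPHABET23

#' Encoding configuration
#'
#' Fixed-length contract for the per-protein input matrices. Sequences
#' longer than `l_max` are truncated at the C-terminus; shorter ones are
#' zero-padded.
#'
#' @param l_max Fixed number of rows of every encoded matrix (default 1000).
#' @param alphabet Ordered 23-letter alphabet (see [protein_alphabet()]).
#' @param pssm_scaling `"none"` (default, raw log-odds are fed to the
#'   network) or `"sigmoid"` (elementwise squashing to (0,1)).
#' @return List of class `subloc_encoding_config`.
#' @export
encoding_config <- function(l_max = 1000L, alphabet = protein_alphabet(),
                            pssm_scaling = c("none", "sigmoid")) {
  pssm_scaling <- match.arg(pssm_scaling)
  l_max <- as.integer(l_max)
  if (is.na(l_max) || l_max < 1L) stop("l_max must be a positive integer")
  if (length(alphabet) != 23L || anyDuplicated(alphabet)) {
    stop("alphabet must be 23 unique letters")
  }
  structure(list(l_max = l_max, alphabet = alphabet,
                 truncation_side = "C-terminal", pssm_scaling = pssm_scaling),
            class = "subloc_encoding_config")
}

# Map a sequence to 1-based alphabet indices (X for unknowns, U->C, O->K).
sequence_to_indices <- function(sequence, config) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  sequence <- toupper(sequence)
  if (!grepl("^[A-Z]+$", sequence)) {
    stop("sequence contains non-letter characters")
  }
  chars <- strsplit(chartr("UO", "CK", sequence), "")[[1]]
  idx <- match(chars, config$alphabet)
  idx[is.na(idx)] <- match("X", config$alphabet)
  idx
}

#' One-hot encode an amino-acid sequence
#'
#' Row i of the result carries a single 1 in the column of residue i; every
#' in-sequence row sums to exactly 1 and padding rows are all-zero.
#'
#' @param sequence Amino-acid string.
#' @param config An [encoding_config()].
#' @return Object of class `subloc_onehot`: list with `values`
#'   (`l_max` x 23 integer matrix, columns named by the alphabet) and
#'   `true_length` (`min(nchar(sequence), l_max)`).
#' @export
#' @examples
#' oh <- one_hot_encode("ACDY", encoding_config(l_max = 6))
#' colSums(oh$values)
one_hot_encode <- function(sequence, config = encoding_config()) {
  idx <- sequence_to_indices(sequence, config)
  n <- min(length(idx), config$l_max)
  values <- matrix(0L, nrow = config$l_max, ncol = 23L,
                   dimnames = list(NULL, config$alphabet))
  values[cbind(seq_len(n), idx[seq_len(n)])] <- 1L
  structure(list(values = values, true_length = n), class = "subloc_onehot")
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()] for sequences of length `<= l_max` (after
#' the U/O/J ambiguity folding, which is not invertible).
#'
#' @param onehot A `subloc_onehot`.
#' @param config The [encoding_config()] used to encode.
#' @return Amino-acid string of length `true_length`.
#' @export
decode_one_hot <- function(onehot, config = encoding_config()) {
  stopifnot(inherits(onehot, "subloc_onehot"))
  n <- onehot$true_length
  if (n == 0L) return("")
  idx <- max.col(onehot$values[seq_len(n), , drop = FALSE])
  paste(config$alphabet[idx], collapse = "")
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue carrying the position index, the residue letter, 20 log-odds
#' scores, 20 weighted observation percentages, the information content and
#' the relative weight of gapless matches (42 numeric columns in file
#' order). Parsing stops at the first blank line after the data block;
#' trailing K/lambda statistics are ignored.
#'
#' @param x Path to a PSSM file, or the file content as a single string /
#'   character vector of lines.
#' @return List with `sequence` (the residue string recovered from column
#'   two, for cross-checking against the FASTA record) and `raw`
#'   (n x 42 numeric matrix).
#' @export
parse_psiblast_pssm <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  # Data rows start with an integer position index followed by one residue
  # letter; locate the first such line.
  toks <- strsplit(trimws(lines), "\\s+")
  is_row_start <- vapply(toks, function(tk) {
    length(tk) >= 2L && grepl("^[0-9]+$", tk[[1]]) &&
      grepl("^[A-Za-z]$", tk[[2]])
  }, logical(1))
  first <- which(is_row_start)[1]
  if (is.na(first)) stop("no PSSM data rows found")
  residues <- character(0)
  rows <- list()
  for (ln in first:length(lines)) {
    tk <- toks[[ln]]
    if (length(tk) == 0L || identical(tk, "")) break  # blank line ends block
    if (!grepl("^[0-9]+$", tk[[1]])) break            # footer statistics
    if (length(tk) != 44L) {
      stop("malformed PSSM row at line ", ln, ": expected 44 fields, got ",
           length(tk))
    }
    vals <- suppressWarnings(as.numeric(tk[3:44]))
    if (anyNA(vals)) {
      stop("non-numeric value in PSSM row at line ", ln)
    }
    residues[[length(residues) + 1L]] <- toupper(tk[[2]])
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no PSSM data rows found")
  raw <- do.call(rbind, rows)
  dimnames(raw) <- NULL
  list(sequence = paste(unlist(residues), collapse = ""), raw = raw)
}

# Inverse of the parser: render a raw n x 42 matrix in the ASCII dialect.
# Used to build fixtures and by cli_simulate for interchange.
format_psiblast_pssm <- function(sequence, raw) {
  stopifnot(ncol(raw) == 42L, nchar(sequence) == nrow(raw))
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(aa20, aa20)), collapse = " "))
  )
  chars <- strsplit(sequence, "")[[1]]
  body <- vapply(seq_len(nrow(raw)), function(i) {
    paste0(sprintf("%5d %s ", i, chars[i]),
           paste(sprintf("%6.2f", raw[i, 1:20]), collapse = ""),
           " ",
           paste(sprintf("%6.2f", raw[i, 21:40]), collapse = ""),
           sprintf("  %5.2f %9.2f", raw[i, 41], raw[i, 42]))
  }, character(1))
  c(header, body, "")
}

#' Normalize a raw PSSM to the fixed network input
#'
#' Pads the 42 numeric columns of the PSI-BLAST output to 43 with a constant
#' zero column (inert padding; users holding 43-column precomputed matrices
#' can feed them through [read_matrix_tsv()] unchanged instead), then pads
#' or truncates rows to `l_max` exactly as [one_hot_encode()] does.
#' Log-odds values outside the usual PSI-BLAST range [-16, 16] trigger a
#' warning, not an error.
#'
#' @param raw n x 42 (or n x 43) numeric matrix.
#' @param config An [encoding_config()]; `pssm_scaling = "sigmoid"` squashes
#'   entries elementwise after padding.
#' @return Object of class `subloc_pssm`: list with `values`
#'   (`l_max` x 43 numeric matrix) and `true_length`.
#' @export
normalize_pssm <- function(raw, config = encoding_config()) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("PSSM contains non-finite entries")
  if (ncol(raw) == 42L) {
    raw <- cbind(raw, 0)
  } else if (ncol(raw) != 43L) {
    stop("raw PSSM must have 42 or 43 columns, got ", ncol(raw))
  }
  if (any(abs(raw[, 1:20]) > 16)) {
    warning("log-odds entries outside [-16, 16]; unusual for PSI-BLAST output")
  }
  n <- min(nrow(raw), config$l_max)
  values <- matrix(0, nrow = config$l_max, ncol = 43L)
  values[seq_len(n), ] <- raw[seq_len(n), ]
  if (config$pssm_scaling == "sigmoid") {
    values[seq_len(n), ] <- sigmoid(values[seq_len(n), , drop = FALSE])
  }
  structure(list(values = values, true_length = n), class = "subloc_pssm")
}

#' Read / write a numeric matrix as TSV
#'
#' Lossless full-precision interchange for precomputed PSSMs and score
#' matrices: plain tab-separated numbers, no header, one row per line.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  rows <- strsplit(trimws(lines), "[\t ]+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows in ", path, ": widths ",
         paste(unique(widths), collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop("non-numeric value in ", path)
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

#' @param matrix Numeric matrix to write.
#' @rdname read_matrix_tsv
#' @return `write_matrix_tsv`: the path, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  lines <- apply(matrix, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
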