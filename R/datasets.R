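# Multi-label protein datasets: construction, IO, summaries, CV folds.

#' Location vocabulary
#'
#' An ordered set of subcellular location names. The order is fixed and
#' defines the column index of every label matrix in the package.
#'
#' @param names Character vector of unique, non-empty location names
#'   (at least 2).
#' @return A character vector of class `subloc_vocabulary`.
#' @export
#' @examples
#' location_vocabulary(c("Nucleus", "Cytoplasm"))
location_vocabulary <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) {
    stop("a location vocabulary needs at least 2 locations, got ",
         length(names))
  }
  if (anyDuplicated(names)) {
    stop("duplicated location name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(!nzchar(names)) || anyNA(names)) {
    stop("location names must be non-empty and non-missing")
  }
  structure(names, class = "subloc_vocabulary")
}

#' Annotated protein set
#'
#' Bundles protein sequences with binary multi-label location annotations
#' against an ordered location vocabulary. Every protein must carry at least
#' one positive label: ranking metrics and the loss are undefined for
#' unlocated proteins, so they are rejected at construction.
#'
#' @param ids Character vector of unique protein identifiers.
#' @param sequences Character vector of amino-acid sequences (standard
#'   residues plus the ambiguity letters B, Z, X, U, O, J).
#' @param labels Binary matrix, one row per protein, one column per location
#'   in vocabulary order.
#' @param vocabulary A [location_vocabulary()] (or character vector).
#' @return An object of class `subloc_proteins` with elements `ids`,
#'   `sequences`, `labels` (0/1 integer matrix with dimnames) and
#'   `vocabulary`.
#' @export
annotated_protein_set <- function(ids, sequences, labels, vocabulary) {
  vocabulary <- if (inherits(vocabulary, "subloc_vocabulary")) vocabulary
                else location_vocabulary(vocabulary)
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(ids)) {
    stop("duplicated protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(sequences) != length(ids)) {
    stop("ids and sequences differ in length")
  }
  labels <- as.matrix(labels)
  if (nrow(labels) != length(ids) || ncol(labels) != length(vocabulary)) {
    stop("labels must be a ", length(ids), " x ", length(vocabulary),
         " matrix, got ", nrow(labels), " x ", ncol(labels))
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  storage.mode(labels) <- "integer"
  bad_seq <- !grepl("^[A-Z]+$", sequences)
  if (any(bad_seq)) {
    stop("empty or non-letter sequence for id(s): ",
         paste(ids[bad_seq], collapse = ", "))
  }
  npos <- rowSums(labels)
  if (any(npos == 0L)) {
    stop("protein(s) with zero location labels: ",
         paste(ids[npos == 0L], collapse = ", "))
  }
  dimnames(labels) <- list(ids, as.character(vocabulary))
  structure(
    list(ids = ids, sequences = setNames(sequences, ids),
         labels = labels, vocabulary = vocabulary),
    class = "subloc_proteins"
  )
}

#' @export
print.subloc_proteins <- function(x, ...) {
  cat("Annotated protein set: ", length(x$ids), " proteins, ",
      length(x$vocabulary), " locations\n", sep = "")
  cat("Locations: ", paste(utils::head(x$vocabulary, 6), collapse = ", "),
      if (length(x$vocabulary) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.subloc_proteins <- function(x) length(x$ids)

# Subset a protein set by id or index, keeping the vocabulary.
#' @export
`[.subloc_proteins` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  annotated_protein_set(x$ids[i], x$sequences[i],
                        x$labels[i, , drop = FALSE], x$vocabulary)
}

parse_label_field <- function(field) {
  out <- strsplit(field, ",", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Load a multi-label protein dataset from FASTA + label table
#'
#' The label table is a two-column TSV without header:
#' `id<TAB>Location1,Location2,...`. FASTA ids (first whitespace-delimited
#' token of each header) and table ids must agree exactly; a protein present
#' in only one of the two files is an error, as is a protein with no label.
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#' @param labels_path Path to the tab-separated label table.
#' @param vocabulary Optional [location_vocabulary()]. When omitted, the
#'   vocabulary is inferred from the label table and ordered by descending
#'   protein count, ties broken alphabetically.
#' @return A [annotated_protein_set()].
#' @export
load_dataset <- function(fasta_path, labels_path, vocabulary = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicated id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tab <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("label table must have two tab-separated columns")
  lab_ids <- tab[[1L]]
  if (anyDuplicated(lab_ids)) {
    stop("duplicated id(s) in label table: ",
         paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
  }
  only_fasta <- setdiff(ids, lab_ids)
  only_table <- setdiff(lab_ids, ids)
  if (length(only_fasta) || length(only_table)) {
    stop("ids present in only one input: ",
         paste(utils::head(c(only_fasta, only_table), 10), collapse = ", "))
  }
  lab_list <- parse_label_field(tab[[2L]])
  names(lab_list) <- lab_ids
  empty <- lengths(lab_list) == 0L
  if (any(empty)) {
    stop("protein(s) with zero location labels: ",
         paste(lab_ids[empty], collapse = ", "))
  }
  all_locs <- unlist(lab_list, use.names = FALSE)
  if (is.null(vocabulary)) {
    counts <- table(all_locs)
    ord <- order(-as.integer(counts), names(counts))
    vocabulary <- location_vocabulary(names(counts)[ord])
  } else {
    vocabulary <- if (inherits(vocabulary, "subloc_vocabulary")) vocabulary
                  else location_vocabulary(vocabulary)
    unknown <- setdiff(unique(all_locs), as.character(vocabulary))
    if (length(unknown)) {
      stop("unknown location name(s) not in vocabulary: ",
           paste(unknown, collapse = ", "))
    }
  }
  L <- length(vocabulary)
  labels <- matrix(0L, nrow = length(ids), ncol = L)
  for (i in seq_along(ids)) {
    labels[i, match(lab_list[[ids[i]]], as.character(vocabulary))] <- 1L
  }
  annotated_protein_set(ids, as.character(seqs), labels, vocabulary)
}

#' Write a dataset back to FASTA + label table
#'
#' Inverse of [load_dataset()]; reloading gives back identical records.
#'
#' @param data A [annotated_protein_set()].
#' @param fasta_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, fasta_path, labels_path) {
  stopifnot(inherits(data, "subloc_proteins"))
  aa <- Biostrings::AAStringSet(unname(data$sequences))
  names(aa) <- data$ids
  Biostrings::writeXStringSet(aa, fasta_path)
  voc <- as.character(data$vocabulary)
  lab <- vapply(seq_along(data$ids), function(i) {
    paste(voc[data$labels[i, ] == 1L], collapse = ",")
  }, character(1))
  writeLines(paste(data$ids, lab, sep = "\t"), labels_path)
  invisible(c(fasta_path, labels_path))
}

#' Composition statistics from per-location counts
#'
#' Summaries that depend only on the published composition of a benchmark:
#' total location assignments, the positive-case rate over the n x L label
#' matrix, and each location's fraction of proteins. This is how the printed
#' benchmark tables (see [benchmark_composition()]) are summarized without
#' the underlying sequences.
#'
#' @param counts Named integer vector of proteins per location.
#' @param n_proteins Number of proteins in the dataset.
#' @return List with `per_location_counts`, `total_assignments`,
#'   `n_proteins`, `n_locations`, `positive_rate` and
#'   `per_location_fraction` (count / n_proteins), unrounded.
#' @export
#' @examples
#' comp <- benchmark_composition("D3106")
#' composition_statistics(comp$counts, comp$n_proteins)$positive_rate
composition_statistics <- function(counts, n_proteins) {
  counts <- unlist(counts)
  if (length(counts) < 1L || any(counts < 0)) stop("invalid counts")
  if (n_proteins < 1L) stop("n_proteins must be positive")
  total <- sum(counts)
  L <- length(counts)
  list(per_location_counts = counts,
       total_assignments = total,
       n_proteins = as.integer(n_proteins),
       n_locations = L,
       positive_rate = total / (n_proteins * L),
       per_location_fraction = counts / n_proteins)
}

#' Dataset statistics
#'
#' Per-location counts, total assignments, positive-case rate, the
#' label-multiplicity histogram (how many proteins carry exactly m labels)
#' and the L x L co-occurrence matrix. The invariants
#' `total = sum(counts) = sum(m * hist[m])` and
#' `diag(cooccurrence) = counts` always hold.
#'
#' @param data A [annotated_protein_set()].
#' @return An object of class `subloc_stats`: the fields of
#'   [composition_statistics()] plus `multiplicity_histogram` (named by m)
#'   and `cooccurrence`.
#' @export
dataset_statistics <- function(data) {
  stopifnot(inherits(data, "subloc_proteins"))
  if (length(data$ids) == 0L) stop("empty protein set")
  Y <- data$labels
  counts <- setNames(as.integer(colSums(Y)), colnames(Y))
  out <- composition_statistics(counts, nrow(Y))
  m <- rowSums(Y)
  hist <- table(factor(m, levels = seq_len(max(m))))
  out$multiplicity_histogram <- setNames(as.integer(hist), names(hist))
  out$cooccurrence <- crossprod(Y)
  class(out) <- "subloc_stats"
  out
}

#' @export
print.subloc_stats <- function(x, digits = 4, ...) {
  cat(sprintf("%d proteins, %d locations, %d assignments (positive rate %s%%)\n",
              x$n_proteins, x$n_locations, x$total_assignments,
              format(round(100 * x$positive_rate, 2))))
  df <- data.frame(
    location = names(x$per_location_counts),
    count = as.integer(x$per_location_counts),
    fraction = sprintf("%.1f%%", 100 * x$per_location_fraction)
  )
  print(df, row.names = FALSE, ...)
  cat("label multiplicity:",
      paste(sprintf("%s:%d", names(x$multiplicity_histogram),
                    x$multiplicity_histogram), collapse = "  "), "\n")
  invisible(x)
}

#' Fractions of multi-location proteins by multiplicity
#'
#' For proteins occupying m >= 2 locations, the fraction each multiplicity
#' class takes of all multi-location proteins. With no multi-location
#' protein the fractions are undefined and reported as `NA`, not zero.
#'
#' @param histogram Named integer vector: number of proteins with exactly m
#'   labels, names are the multiplicities.
#' @return List with `counts` (the m >= 2 classes) and `fraction` (same
#'   names; `NA` when undefined).
#' @export
#' @examples
#' multiplicity_fractions(c(`1` = 2580, `2` = 480, `3` = 43, `4` = 3))
multiplicity_fractions <- function(histogram) {
  m <- as.integer(names(histogram))
  if (anyNA(m)) stop("histogram must be named by multiplicity")
  keep <- m >= 2L & histogram > 0
  counts <- histogram[keep]
  total <- sum(counts)
  frac <- if (total > 0) counts / total else
    setNames(rep(NA_real_, length(counts)), names(counts))
  list(counts = counts, fraction = frac)
}

#' Multi-location composition of a dataset
#'
#' @param data A [annotated_protein_set()].
#' @return As [multiplicity_fractions()], computed from the set's
#'   label-multiplicity histogram.
#' @export
multilocation_summary <- function(data) {
  stats <- dataset_statistics(data)
  multiplicity_fractions(stats$multiplicity_histogram)
}

#' Cross-validation folds
#'
#' Uniform random partition of the protein ids into k folds whose sizes
#' differ by at most one; deterministic for a fixed seed. Stratification by
#' the rarest positive label of each protein is available as an option.
#'
#' @param data A [annotated_protein_set()], or a character vector of ids.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed controlling the shuffle.
#' @param stratify Logical; when `TRUE` proteins are dealt to folds within
#'   groups sharing the same rarest label, balancing scarce locations.
#' @return List of k lists, each with `train` and `test` character id
#'   vectors; the test sets partition the ids.
#' @export
cross_validation_folds <- function(data, k, seed = 1L, stratify = FALSE) {
  ids <- if (inherits(data, "subloc_proteins")) data$ids else as.character(data)
  n <- length(ids)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= ", n, ", got ", k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # canonical order first: folds are a function of the id SET and the seed,
  # never of input order
  sorted <- sort(ids)
  if (stratify && inherits(data, "subloc_proteins")) {
    labels <- data$labels[match(sorted, data$ids), , drop = FALSE]
    counts <- colSums(labels)
    rare <- apply(labels, 1L, function(r) {
      pos <- which(r == 1L)
      pos[which.min(counts[pos])]
    })
    shuffled <- sorted[order(rare, sample.int(n))]
  } else {
    shuffled <- sorted[sample.int(n)]
  }
  assign <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    test <- shuffled[assign == f]
    list(train = setdiff(ids, test), test = test)
  })
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Published benchmark compositions
#'
#' The per-location protein counts of the two standard human-protein
#' benchmarks used in this literature: D3106 (3106 proteins over 14
#' locations, 3681 assignments) and D4802 (4802 proteins over 33 locations,
#' 6198 assignments), plus D3106's multi-location histogram (480 proteins in
#' two locations, 43 in three, 3 in four). These printed tables let the
#' composition summaries be reproduced without downloading the deposited
#' sequence data.
#'
#' @param name `"D3106"` or `"D4802"`.
#' @return List with `counts` (named integer vector), `n_proteins`, and for
#'   D3106 `multilocation` (proteins with exactly 2, 3, 4 locations).
#' @export
benchmark_composition <- function(name = c("D3106", "D4802")) {
  name <- match.arg(name)
  if (name == "D3106") {
    counts <- c(
      Nucleus = 1021L, Cytoplasm = 817L, Extracellular = 385L,
      Mitochondrion = 364L, `Plasma membrane` = 354L,
      `Endoplasmic reticulum` = 229L, `Golgi apparatus` = 161L,
      Cytoskeleton = 79L, Centriole = 77L, Lysosome = 77L,
      Peroxisome = 47L, Endosome = 24L, Microsome = 24L, Synapse = 22L
    )
    list(counts = counts, n_proteins = 3106L,
         multilocation = c(`2` = 480L, `3` = 43L, `4` = 3L))
  } else {
    counts <- c(
      Nucleus = 1720L, Cytoplasm = 1050L, `Plasma membrane` = 836L,
      Extracellular = 487L, Mitochondria = 407L, Endosome = 342L,
      `Golgi apparatus` = 272L, Nucleolus = 268L, Lysosomes = 125L,
      `Endoplasmic reticulum` = 120L, Cytoskeleton = 89L, Centrosome = 81L,
      Peroxisome = 67L, `Early endosomes` = 52L, `Nuclear envelope` = 47L,
      `Cytoplasmic vesicles` = 46L, `Basolateral plasma membrane` = 29L,
      `Synaptic vesicles` = 28L, Microtubule = 26L,
      `Apical plasma membrane` = 16L, `Late endosomes` = 16L,
      `Golgi trans face` = 11L, `Secretory granule` = 10L,
      `Tight junction` = 9L, `Golgi cis cisterna` = 7L, `Medial-golgi` = 7L,
      Melanosome = 6L, `Secretory vesicles` = 5L, `Cellular component` = 4L,
      ERGIC = 4L, `Inner mitochondrial membrane` = 4L,
      `Transport vesicle` = 4L, `Golgi trans cisterna` = 3L
    )
    list(counts = counts, n_proteins = 4802L)
  }
}
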