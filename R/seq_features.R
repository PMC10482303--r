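# Sequence-profile parsers, their transforms, and embedding-table ingestion.

.pssm_alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the 20-column integer log-odds block of `-out_ascii_pssm` output.
#'
#' @param path File path.
#' @return A `profile_matrix`: list with `kind = "PSSM"`, `values` (N x 20),
#'   `alphabet`, `seq`.
#' @export
parse_pssm <- function(path) {
  lines <- readLines(path)
  alphabet <- .pssm_alphabet
  rows <- list(); seq <- character()
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(toks) >= 2 && grepl("^\\d+$", toks[1]) && grepl("^[A-Zx]$", toks[2])) {
      if (length(toks) < 22) stop("truncated PSSM row at line ", k)
      vals <- suppressWarnings(as.numeric(toks[3:22]))
      if (anyNA(vals)) stop("non-numeric PSSM value at line ", k)
      rows[[length(rows) + 1]] <- vals
      seq <- c(seq, toks[2])
    } else if (length(toks) >= 20 && all(grepl("^[A-Z]$", toks))) {
      alphabet <- toks[1:20]
    }
  }
  if (!length(rows)) stop("no PSSM data rows found in ", path)
  structure(
    list(kind = "PSSM", values = do.call(rbind, rows), alphabet = alphabet, seq = seq),
    class = "profile_matrix"
  )
}

#' Write a PSSM in PSI-BLAST-like ASCII layout (round-trip support)
#'
#' @param profile `profile_matrix` of kind PSSM.
#' @param path File path.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(profile$kind == "PSSM")
  con <- file(path, "w")
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed", con)
  writeLines(paste0("            ", paste(sprintf("%3s", profile$alphabet), collapse = " ")), con)
  for (i in seq_len(nrow(profile$values))) {
    writeLines(paste0(
      sprintf("%5d %s  ", i, profile$seq[i]),
      paste(sprintf("%3d", as.integer(round(profile$values[i, ]))), collapse = " ")
    ), con)
  }
  close(con)
  invisible(path)
}

#' Sigmoid normalisation of a PSSM
#'
#' Elementwise `1 / (1 + exp(-x))` of the log-odds scores.
#'
#' @param profile `profile_matrix` of kind PSSM.
#' @return N x 20 matrix in (0, 1), columns `pssm_<aa>`.
#' @export
pssm_sigmoid <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"), profile$kind == "PSSM")
  out <- 1 / (1 + exp(-profile$values))
  colnames(out) <- paste0("pssm_", profile$alphabet)
  out
}

#' Parse an HHsuite .hhm profile
#'
#' Reads the 20 emission columns of each match state; the sentinel `*`
#' (impossible emission) becomes `NA` and maps to probability 0 under
#' [hmm_inverse_transform()]. Transition columns are excluded.
#'
#' @param path File path.
#' @return A `profile_matrix` with `kind = "HMM"`.
#' @export
parse_hhm <- function(path) {
  lines <- readLines(path)
  start <- grep("^HMM\\s", lines)
  if (!length(start)) stop("no HMM block found in ", path)
  alphabet <- strsplit(trimws(sub("^HMM\\s*", "", lines[start[1]])), "\\s+")[[1]]
  alphabet <- sub("->.*", "", alphabet)[1:20]
  rows <- list(); seq <- character()
  k <- start[1] + 1
  while (k <= length(lines)) {
    line <- trimws(lines[k])
    if (line == "//") break
    toks <- strsplit(line, "\\s+")[[1]]
    if (length(toks) >= 22 && grepl("^[A-Z]$", toks[1]) && grepl("^\\d+$", toks[2])) {
      vals <- toks[3:22]
      num <- suppressWarnings(as.numeric(vals))
      if (any(is.na(num) & vals != "*")) stop("bad emission value at line ", k)
      num[vals == "*"] <- NA_real_
      rows[[length(rows) + 1]] <- num
      seq <- c(seq, toks[1])
    }
    k <- k + 1
  }
  if (!length(rows)) stop("no match states found in ", path)
  structure(
    list(kind = "HMM", values = do.call(rbind, rows), alphabet = alphabet, seq = seq),
    class = "profile_matrix"
  )
}

#' Write an .hhm-style profile (round-trip support)
#'
#' @param profile `profile_matrix` of kind HMM; `NA` entries are written as `*`.
#' @param path File path.
#' @export
write_hhm <- function(profile, path) {
  stopifnot(profile$kind == "HMM")
  con <- file(path, "w")
  writeLines("HHsearch 1.5", con)
  writeLines("NULL   3706 5728 4211 4064 4839 3729 4763 4308 4069 3323 5509 4640 4464 4937 4285 4423 3815 3783 6325 4665", con)
  writeLines(paste("HMM   ", paste(profile$alphabet, collapse = "\t")), con)
  writeLines("       M->M\tM->I\tM->D\tI->M\tI->I\tD->M\tD->D\tNeff\tNeff_I\tNeff_D", con)
  for (i in seq_len(nrow(profile$values))) {
    v <- profile$values[i, ]
    txt <- ifelse(is.na(v), "*", sprintf("%d", as.integer(round(v))))
    writeLines(paste(profile$seq[i], i, paste(txt, collapse = "\t"), i, sep = "\t"), con)
    writeLines("\t0\t*\t*\t*\t*\t*\t*\t1000\t0\t0", con)
  }
  writeLines("//", con)
  close(con)
  invisible(path)
}

#' Inverse transform of HMM emission scores
#'
#' The .hhm convention stores emissions as `-1000 * log2(p)`; the transform
#' `2^(-0.001 x)` recovers probabilities, with `*`/`NA` (impossible state)
#' mapped to 0.
#'
#' @param profile `profile_matrix` of kind HMM.
#' @return N x 20 matrix in \[0, 1\], columns `hmm_<aa>`.
#' @export
hmm_inverse_transform <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"), profile$kind == "HMM")
  out <- 2^(-0.001 * profile$values)
  out[is.na(out)] <- 0
  colnames(out) <- paste0("hmm_", profile$alphabet)
  out
}

#' Load a per-residue embedding table
#'
#' Headered TSV: `residue_id` plus D numeric columns (e.g. externally
#' computed language-model or inverse-folding embeddings).
#'
#' @param path TSV file.
#' @param expected_n Required row count (protein length).
#' @return N x D numeric matrix.
#' @export
load_embeddings <- function(path, expected_n) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(df) != expected_n) {
    stop(sprintf("embedding table has %d rows, expected %d", nrow(df), expected_n))
  }
  m <- as.matrix(df[, setdiff(names(df), "residue_id"), drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m))) stop("embedding table must be finite numeric")
  m
}
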