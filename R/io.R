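#' Read a pedigree file
#'
#' Whitespace- or comma-separated file with columns animal, sire, dam and an
#' optional fourth column sex; `0` codes an unknown parent.  A header line is
#' detected and skipped.
#'
#' @param path file path.
#' @return a sorted `pedigree`.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("animal", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character",
                          strip.white = TRUE, blank.lines.skip = TRUE)
  sort_pedigree(df)
}

#' Read genotype dosages
#'
#' Auto-detects two dialects: (A) one line per animal, `ID` followed by a
#' fixed-width string of 0/1/2 dosages (`5` or `NA` not allowed; missing
#' dosage coded `9` is imputed); (B) CSV with a header `ID,m1,...,mk`.
#'
#' @param path file path.
#' @param allele_freq optional per-marker allele frequencies.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, allele_freq = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1L]])
    dos <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    ids <- vapply(parts, `[[`, "", 1L)
    strs <- vapply(parts, `[[`, "", 2L)
    if (length(unique(nchar(strs))) != 1L)
      stop("dosage strings have unequal length")
    dos <- do.call(rbind, lapply(strsplit(strs, ""), as.integer))
  }
  dos[dos == 9] <- NA_integer_
  genotype_matrix(dos, ids = ids, allele_freq = allele_freq)
}

#' Read a records file
#'
#' CSV with a header containing an `animal` column, one column per declared
#' fixed effect and one column per trait; empty fields or `NA` are missing
#' trait values.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an analysis parameter file
#'
#' YAML key/value file with entries such as `sigma_u2`, `sigma_e2` (single
#' trait) or `G0` / `R0` (row-major lists), `n_core`, `seed`, `beta`, `tol`.
#'
#' @param path file path.
#' @return list with a `vc` element (`variance_components`) plus all other
#'   entries verbatim.
#' @export
read_params <- function(path) {
  prm <- yaml::read_yaml(path)
  if (!is.null(prm$G0)) {
    nt <- as.integer(sqrt(length(unlist(prm$G0))))
    vc <- variance_components(
      G0 = matrix(unlist(prm$G0), nt, nt, byrow = TRUE),
      R0 = matrix(unlist(prm$R0), nt, nt, byrow = TRUE))
  } else {
    vc <- variance_components(sigma_u2 = prm$sigma_u2,
                              sigma_e2 = prm$sigma_e2)
  }
  c(list(vc = vc), prm[setdiff(names(prm), c("sigma_u2", "sigma_e2",
                                             "G0", "R0"))])
}

#' Write a reliability table
#'
#' Writes the per-animal, per-trait staged reliabilities of a fit to CSV.
#'
#' @param fit an `ssgblup_rel` object.
#' @param path output file path.
#' @export
write_reliabilities <- function(fit, path) {
  utils::write.csv(fit$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
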