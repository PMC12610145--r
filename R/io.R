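# Plain-text image I/O. Slices are written as ASCII PGM (P2): 16-bit range
# for intensity images, {0, 255} for masks. Cohort manifests are CSV.

#' Read and write ASCII PGM images
#'
#' `write_pgm()` quantizes a \[0, 1\] image to `maxval` levels; `read_pgm()`
#' restores it to \[0, 1\]. Masks round-trip exactly when written with
#' `maxval = 255` from hard 0/1 values.
#'
#' @param image matrix with values in \[0, 1\].
#' @param path file path.
#' @param maxval maximum gray level (65535 for intensity images, 255 for masks).
#' @return `read_pgm()` returns a numeric matrix in \[0, 1\] (values / maxval).
#' @export
write_pgm <- function(image, path, maxval = 65535) {
  x <- round(unclass(image) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
  # PGM is row-major, top row first
  write(t(x), file = con, ncolumns = min(ncol(x), 16))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") abort("read_pgm: only ASCII PGM (P2) is supported")
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a generated cohort to disk
#'
#' Materializes every slice of every patient as PGM files (image + mask) plus
#' a CSV manifest with one row per slice: `patient_id`, `slice_index`, `file`,
#' `mask_file`, `true_diameter_mm`, `true_class`.
#'
#' @param cohort a cohort manifest from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest tibble (invisibly), as written to `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    slices <- generate_patient_slices(cohort, i)
    purrr::map_dfr(seq_along(slices), function(j) {
      s <- slices[[j]]
      f <- sprintf("%s_s%03d.pgm", cohort$patient_id[i], j - 1L)
      fm <- sprintf("%s_s%03d_mask.pgm", cohort$patient_id[i], j - 1L)
      write_pgm(s$image, file.path(dir, f), maxval = 65535)
      write_pgm(s$mask, file.path(dir, fm), maxval = 255)
      tibble::tibble(
        patient_id = cohort$patient_id[i], slice_index = j - 1L,
        file = f, mask_file = fm,
        true_diameter_mm = s$true_diameter_mm,
        true_class = as.character(cohort$true_class[i])
      )
    })
  })
  readr::write_csv(rows, file.path(dir, "manifest.csv"))
  invisible(rows)
}
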