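#' Write a study set to a directory of CSV matrices plus a JSON manifest
#'
#' The exchange format for externally supplied meta-analyses: one CSV
#' file per study (4x4 correlation matrix with variable-name header) and
#' a `manifest.json` listing, per study, the file name, sample size and
#' population label.
#'
#' @param x A [study_set()].
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly.
#' @export
write_studyset <- function(x, dir) {
  stopifnot(inherits(x, "study_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("study_%02d.csv", seq_along(x$n))
  for (i in seq_along(x$n)) {
    R <- x$R[[i]]
    dimnames(R) <- list(.var_names, .var_names)
    utils::write.csv(R, file.path(dir, files[i]), row.names = TRUE)
  }
  manifest <- list(studies = data.frame(file = files, n = x$n,
                                        label = x$labels,
                                        stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study set from the CSV + manifest exchange format
#'
#' @param dir Directory written by [write_studyset()] (or assembled by
#'   hand in the same layout).
#' @return A [study_set()].
#' @export
read_studyset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  st <- manifest$studies
  R <- lapply(st$file, function(f) {
    m <- utils::read.csv(file.path(dir, f), row.names = 1)
    as.matrix(m)
  })
  study_set(st$n, R, st$label)
}
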