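# Plugin discovery: content analyzers self-describe the file types they
# apply to and are activated from the header chunk's filename extension,
# with magic-byte sniffing as fallback and manual override.

#' Built-in content plugin registry
#'
#' Each plugin provides `name`, `applicable(filename, first_bytes)` and
#' `analyze(dr, ...)`.  Additional plugins can be supplied to
#' [detect_plugin()] via the `extra` argument.
#'
#' @return named list of plugin descriptors
#' @export
plugin_registry <- function() {
  list(
    zip = list(
      name = "zip",
      applicable = function(filename, first_bytes) {
        grepl("\\.(zip|jar|docx|xlsx)$", filename, ignore.case = TRUE) ||
          (length(first_bytes) >= 4 &&
           identical(first_bytes[1:4], SIG_LOCAL))
      },
      analyze = function(dr, ...) zip_analyze(dr)
    ),
    bmp = list(
      name = "bmp",
      applicable = function(filename, first_bytes) {
        grepl("\\.bmp$", filename, ignore.case = TRUE) ||
          (length(first_bytes) >= 2 &&
           rawToChar(first_bytes[1:2]) %in% BMP_SIGNATURES)
      },
      analyze = function(dr, ...) bmp_analyze(dr)
    ),
    text = list(
      name = "text",
      applicable = function(filename, first_bytes) {
        grepl("\\.(txt|md|csv|text)$", filename, ignore.case = TRUE) ||
          (length(first_bytes) > 0 &&
           mean(first_bytes >= as.raw(0x20) & first_bytes < as.raw(0x7f) |
                first_bytes %in% as.raw(c(9, 10, 13))) > 0.95)
      },
      analyze = function(dr, corrector, ...) {
        rows <- which(dr$system$solved_mask[seq_len(dr$n_chunks)])
        rows <- setdiff(rows, 1L)  # skip the header chunk
        text_error_histogram(dr$solution, corrector, rows = rows)
      }
    )
  )
}

#' Pick the content plugin for a decode result
#'
#' Uses the filename stored in the header chunk, falling back to
#' magic-byte sniffing of the first decoded bytes.
#'
#' @param dr a `decode_result`
#' @param override plugin name to force, skipping detection
#' @param extra additional plugin descriptors tried before the built-ins
#' @return a plugin descriptor or `NULL` when nothing applies
#' @export
detect_plugin <- function(dr, override = NULL, extra = list()) {
  reg <- c(extra, plugin_registry())
  if (!is.null(override)) {
    if (!override %in% names(reg)) stop("unknown plugin: ", override)
    return(reg[[override]])
  }
  filename <- if (!is.null(dr$header)) dr$header$filename else ""
  first_bytes <- if (!is.null(dr$file)) utils::head(dr$file, 64) else {
    cs <- ncol(dr$solution)
    dr$solution[min(2, nrow(dr$solution)), seq_len(min(64, cs))]
  }
  for (p in reg) {
    if (isTRUE(p$applicable(filename, first_bytes))) return(p)
  }
  NULL
}
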