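#' Default FAME retention-time library
#'
#' Retention-time reference for the fatty-acid methyl esters routinely
#' resolved on a GC-FID apolar column in yeast lipid work: C14:0, C16:0,
#' C16:1(n-7), the C17:0 internal standard, C18:0, C18:1(n-9) and
#' C18:2(n-6), at one-minute spacings. Response factors default to 1
#' (uniform FID response across FAMEs).
#'
#' @return A data frame of class `rt_library` with columns `fa_name`,
#'   `rt_min`, `response_factor`, `is_internal_standard`.
#' @export
#' @examples
#' default_rt_library()
default_rt_library <- function() {
  lib <- data.frame(
    fa_name = c("C14:0", "C16:0", "C16:1(n-7)", "C17:0", "C18:0",
                "C18:1(n-9)", "C18:2(n-6)"),
    rt_min = c(3, 4, 5, 6, 7, 8, 9),
    response_factor = 1,
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  validate_rt_library(lib)
}

#' Read a retention-time library from CSV
#'
#' Expected columns: `fa_name`, `rt_min`, `response_factor`,
#' `is_internal_standard` (logical or 0/1). Exactly one entry must be
#' flagged as the internal standard.
#'
#' @param path Path to a CSV file.
#' @return An `rt_library` data frame.
#' @export
read_rt_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("fa_name", "rt_min", "response_factor", "is_internal_standard")
  miss <- setdiff(req, names(lib))
  if (length(miss))
    stop_config("RT library %s lacks column(s): %s", path,
                paste(miss, collapse = ", "))
  lib$is_internal_standard <- as.logical(lib$is_internal_standard)
  validate_rt_library(lib[req])
}

validate_rt_library <- function(lib) {
  if (sum(lib$is_internal_standard) != 1L)
    stop_config("RT library must contain exactly one internal-standard entry")
  if (anyDuplicated(lib$rt_min))
    stop_config("RT library retention times must be unique")
  if (anyDuplicated(lib$fa_name))
    stop_config("RT library FA names must be unique")
  if (any(lib$response_factor <= 0))
    stop_config("response factors must be positive")
  class(lib) <- c("rt_library", "data.frame")
  lib
}

is_entry <- function(lib) lib[lib$is_internal_standard, , drop = FALSE]
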