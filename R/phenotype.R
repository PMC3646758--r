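#' Construct / read a strain-by-substrate phenotype matrix
#'
#' Categorical growth scores from drop tests and assimilation galleries,
#' kept in long format: one row per strain x substrate x medium with a
#' four-level score (`growth`, `weak`, `none`, `untested`; the study's
#' "delayed, weak or slow" collapse to `weak`) and an optional halo flag
#' for insoluble-substrate plates. The medium is either minimal base
#' (`MMB`) or rich base (`YP`); the rich base alone is encoded as
#' substrate `"none"` and serves as the growth control for toxicity
#' calls.
#'
#' @param df Data frame with columns `strain`, `substrate`,
#'   `substrate_class`, `medium`, `score`, and optionally `halo`
#'   (logical, `NA` where halos were not scored).
#' @return A `phenotype_matrix` data frame.
#' @export
phenotype_matrix <- function(df) {
  req <- c("strain", "substrate", "medium", "score")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_config("phenotype matrix lacks column(s): %s",
                paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$score), c("growth", "weak", "none", "untested"))
  if (length(bad))
    stop_config("invalid score value(s): %s", paste(bad, collapse = ", "))
  if (is.null(df$substrate_class)) df$substrate_class <- NA_character_
  if (is.null(df$halo)) df$halo <- NA
  df$halo <- as.logical(df$halo)
  key <- interaction(df$strain, df$substrate, df$medium, drop = TRUE)
  if (anyDuplicated(key))
    stop_config("duplicate strain x substrate x medium entries")
  class(df) <- c("phenotype_matrix", "data.frame")
  df
}

#' @rdname phenotype_matrix
#' @param path Long-format TSV path (`strain`, `substrate`,
#'   `substrate_class`, `medium`, `score`, `halo`).
#' @export
read_phenotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  phenotype_matrix(df)
}

#' @rdname phenotype_matrix
#' @param matrix A `phenotype_matrix`.
#' @export
write_phenotype_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition substrates into universal / unused / variable
#'
#' For one medium, splits the tested substrates into those supporting the
#' growth of every strain (universal), those supporting no strain
#' (unused), and the rest (variable) — the three-way summary of an
#' assimilation survey. The rich-base control substrate `"none"` is
#' excluded.
#'
#' @param matrix A [phenotype_matrix()].
#' @param medium Medium to summarise (default `"MMB"`).
#' @param weak_counts_as_growth Treat `weak` scores as growth (default
#'   `TRUE`, as when weak growers are counted among users of a
#'   substrate).
#' @return A `substrate_summary` list with character vectors `universal`,
#'   `unused`, `variable` (a partition of the tested substrates).
#' @export
summarize_substrates <- function(matrix, medium = "MMB",
                                 weak_counts_as_growth = TRUE) {
  stopifnot(inherits(matrix, "phenotype_matrix"))
  m <- matrix[matrix$medium == medium & matrix$substrate != "none", ]
  if (!nrow(m)) stop_config("no scores recorded for medium '%s'", medium)
  strains <- unique(m$strain)
  substrates <- unique(m$substrate)
  full <- expand.grid(strain = strains, substrate = substrates,
                      stringsAsFactors = FALSE)
  key <- paste(m$strain, m$substrate, sep = "\r")
  idx <- match(paste(full$strain, full$substrate, sep = "\r"), key)
  if (anyNA(idx) || any(m$score[idx] == "untested")) {
    missing <- full[is.na(idx) | m$score[idx] == "untested", , drop = FALSE]
    stop_config("untested strain x substrate combination(s): %s",
                paste(paste(missing$strain, missing$substrate, sep = " x "),
                      collapse = "; "))
  }
  grows_lv <- if (weak_counts_as_growth) c("growth", "weak") else "growth"
  universal <- character(); unused <- character(); variable <- character()
  for (s in substrates) {
    sc <- m$score[m$substrate == s]
    if (all(sc %in% grows_lv)) universal <- c(universal, s)
    else if (all(sc == "none")) unused <- c(unused, s)
    else variable <- c(variable, s)
  }
  structure(list(universal = universal, unused = unused,
                 variable = variable, medium = medium,
                 n_strains = length(strains)),
            class = "substrate_summary")
}

#' @export
print.substrate_summary <- function(x, ...) {
  cat(sprintf("Substrate summary (%s, %d strains, %d substrates)\n",
              x$medium, x$n_strains,
              length(x$universal) + length(x$unused) + length(x$variable)))
  cat(sprintf("  universal (%d): %s\n", length(x$universal),
              paste(x$universal, collapse = ", ")))
  cat(sprintf("  unused    (%d)\n", length(x$unused)))
  cat(sprintf("  variable  (%d): %s\n", length(x$variable),
              paste(x$variable, collapse = ", ")))
  invisible(x)
}

#' Strains forming a halo on a given substrate plate
#'
#' A halo around colonies on an insoluble substrate reflects secretion of
#' surfactants or extracellular lipases/esterases.
#'
#' @param matrix A [phenotype_matrix()].
#' @param substrate Substrate name.
#' @param medium Medium (`"MMB"` or `"YP"`).
#' @return Character vector of strains with the halo flag set; empty
#'   (with a warning) when no halo data exist for the substrate.
#' @export
halo_table <- function(matrix, substrate, medium = "YP") {
  stopifnot(inherits(matrix, "phenotype_matrix"))
  m <- matrix[matrix$substrate == substrate & matrix$medium == medium, ]
  if (!nrow(m) || all(is.na(m$halo))) {
    warning(sprintf("no halo data for '%s' on %s", substrate, medium),
            call. = FALSE)
    return(character())
  }
  sort(unique(m$strain[!is.na(m$halo) & m$halo]))
}

#' Toxicity and non-metabolisation flags for substrates
#'
#' Distinguishes the three reasons a substrate may fail to support
#' growth. For each strain, a substrate is *toxic* when the strain does
#' not grow on rich medium plus the substrate although it grows on rich
#' medium alone (the substrate inhibits growth outright); it is
#' *non-metabolised* when the strain fails on minimal medium plus the
#' substrate but grows on rich medium plus the substrate (the substrate
#' is tolerated but not used as a carbon source).
#'
#' @param matrix A [phenotype_matrix()] containing MMB and YP scores for
#'   the substrates plus YP-alone control rows (substrate `"none"`,
#'   medium `"YP"`).
#' @param weak_counts_as_growth Treat `weak` as growth (default `TRUE`).
#' @return A data frame, one row per substrate: `substrate`, `toxic`
#'   (TRUE when toxic to at least one strain), `toxic_all`,
#'   `non_metabolized` (TRUE when at least one strain tolerates but does
#'   not use it).
#' @export
toxicity_flags <- function(matrix, weak_counts_as_growth = TRUE) {
  stopifnot(inherits(matrix, "phenotype_matrix"))
  ctrl <- matrix[matrix$substrate == "none" & matrix$medium == "YP", ]
  if (!nrow(ctrl))
    stop_config("missing YP-alone control rows (substrate 'none')")
  grows_lv <- if (weak_counts_as_growth) c("growth", "weak") else "growth"
  ctrl_grows <- stats::setNames(ctrl$score %in% grows_lv, ctrl$strain)
  substrates <- setdiff(unique(matrix$substrate), "none")
  out <- data.frame(substrate = substrates, toxic = FALSE,
                    toxic_all = FALSE, non_metabolized = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(substrates)) {
    s <- substrates[i]
    yp <- matrix[matrix$substrate == s & matrix$medium == "YP", ]
    mmb <- matrix[matrix$substrate == s & matrix$medium == "MMB", ]
    if (!nrow(yp) || !nrow(mmb))
      stop_config("substrate '%s' lacks scores on both MMB and YP", s)
    strains <- intersect(yp$strain, names(ctrl_grows))
    if (!length(strains))
      stop_config("no YP-alone control for strains tested on '%s'", s)
    yp_sc <- stats::setNames(yp$score, yp$strain)[strains]
    mmb_sc <- stats::setNames(mmb$score, mmb$strain)[strains]
    tox <- yp_sc == "none" & ctrl_grows[strains]
    nonmet <- mmb_sc == "none" & yp_sc %in% grows_lv
    out$toxic[i] <- any(tox)
    out$toxic_all[i] <- all(tox)
    out$non_metabolized[i] <- any(nonmet)
  }
  out
}
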