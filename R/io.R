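## Readers and writers for the plain-text table dialects the pipeline
## consumes. Concentration columns carry their unit in the header
## (l0_uM, conc_mM): the source experiments mix micromolar and millimolar
## and silent unit guessing is forbidden.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = TRUE, comment.char = "")
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stopf("%s: missing required column(s) %s", path,
          paste(miss, collapse = ", "))
}

## numeric conversion that names the offending file line (+1 for header)
num_col <- function(df, col, path, allow_dash = FALSE) {
  raw <- df[[col]]
  dash <- trimws(raw) == "-"
  v <- suppressWarnings(as.numeric(raw))
  bad <- is.na(v) & !dash
  if (any(bad))
    stopf("%s line %d: non-numeric value '%s' in column %s",
          path, which(bad)[1] + 1L, raw[which(bad)[1]], col)
  if (!allow_dash && any(dash))
    stopf("%s line %d: '-' not allowed in column %s",
          path, which(dash)[1] + 1L, col)
  v
}

#' Read a long-format STD peak table into build-up curves
#'
#' Expects columns `ligand_id, proton_label, t_sat_s, std_fraction`
#' (CSV, or TSV by file extension). A `std_fraction` of `"-"` marks an
#' unintegrable proton: all its rows are skipped with a warning, following
#' the usual report convention for overlapping peaks. Duplicate
#' (proton, time) pairs and non-numeric cells are parse errors naming the
#' offending line.
#'
#' @param path file path.
#' @return named list of [buildup_curve]s, keyed `ligand_id/proton_label`.
#' @export
read_peak_table <- function(path) {
  df <- read_delim_auto(path)
  need_cols(df, c("ligand_id", "proton_label", "t_sat_s", "std_fraction"),
            path)
  t_sat <- num_col(df, "t_sat_s", path)
  stdf <- num_col(df, "std_fraction", path, allow_dash = TRUE)
  key <- paste(df$ligand_id, df$proton_label, sep = "/")
  dup <- duplicated(cbind(key, t_sat))
  if (any(dup))
    stopf("%s line %d: duplicate (proton, time) pair %s @ %gs",
          path, which(dup)[1] + 1L, key[which(dup)[1]], t_sat[which(dup)[1]])
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    if (any(is.na(stdf[rows]))) {
      warnf("%s: proton %s has '-' entries; skipped as unintegrable", path, k)
      next
    }
    ord <- rows[order(t_sat[rows])]
    out[[k]] <- buildup_curve(t_sat[ord], stdf[ord],
                              proton_label = df$proton_label[ord[1]],
                              ligand_id = df$ligand_id[ord[1]])
  }
  if (length(out) == 0) stopf("%s: no usable protons", path)
  out
}

#' Read a long-format inversion-recovery table
#'
#' Expects columns `ligand_id, l0_uM, p0_uM, delay_s, intensity`.
#'
#' @param path file path.
#' @return list of [ir_trace]s, one per (ligand_id, l0_uM).
#' @export
read_ir_table <- function(path) {
  df <- read_delim_auto(path)
  need_cols(df, c("ligand_id", "l0_uM", "p0_uM", "delay_s", "intensity"),
            path)
  l0 <- num_col(df, "l0_uM", path)
  p0 <- num_col(df, "p0_uM", path)
  dl <- num_col(df, "delay_s", path)
  it <- num_col(df, "intensity", path)
  key <- paste(df$ligand_id, l0)
  lapply(unique(key), function(k) {
    rows <- which(key == k)
    ord <- rows[order(dl[rows])]
    ir_trace(dl[ord], it[ord], ligand_conc_uM = l0[ord[1]],
             protein_conc_uM = p0[ord[1]], ligand_id = df$ligand_id[ord[1]])
  })
}

#' Write build-up curves in the long-format dialect [read_peak_table] reads
#'
#' @param curves list of [buildup_curve]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(ligand_id = cv$ligand_id, proton_label = cv$proton_label,
               t_sat_s = cv$saturation_times,
               std_fraction = cv$std_fractions,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write inversion-recovery traces in the dialect [read_ir_table] reads
#'
#' @param traces list of [ir_trace]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ir_table <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(ligand_id = tr$ligand_id, l0_uM = tr$ligand_conc,
               p0_uM = tr$protein_conc, delay_s = tr$recovery_delays,
               intensity = tr$intensities, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spin system to the fixture JSON schema
#'
#' One record per proton: `{label, owner, xyz, methyl_id, saturated}`.
#'
#' @param system a [spin_system].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(system, path) {
  lig <- system$owner == "ligand"
  recs <- lapply(seq_along(system$labels), function(i) {
    list(label = system$labels[i], owner = system$owner[i],
         xyz = as.numeric(system$xyz_bound[i, ]),
         methyl_id = if (is.na(system$methyl_id[i])) NULL else
           system$methyl_id[i],
         saturated = system$saturated[i])
  })
  jsonlite::write_json(list(protons = recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a spin system from the fixture JSON schema
#'
#' @param path JSON path written by [write_spin_system].
#' @return a [spin_system].
#' @export
read_spin_system <- function(path) {
  js <- jsonlite::read_json(path)
  p <- js$protons
  if (is.null(p) || length(p) == 0) stopf("%s: no protons", path)
  spin_system(
    labels = vapply(p, `[[`, character(1), "label"),
    owner = vapply(p, `[[`, character(1), "owner"),
    xyz_bound = t(vapply(p, function(r) as.numeric(unlist(r$xyz)),
                         numeric(3))),
    methyl_id = vapply(p, function(r)
      if (is.null(r$methyl_id)) NA_character_ else as.character(r$methyl_id),
      character(1)),
    saturated = vapply(p, function(r) isTRUE(r$saturated), logical(1)))
}
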