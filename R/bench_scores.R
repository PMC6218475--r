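# Closed-form assay scores: IgG Fc N-glycan sialylation and galactosylation
# read-outs from capillary-electrophoresis peak heights, and the transwell
# chemotaxis migration index.

.glycan_peak_names <- c("G0F", "G1F_1", "G1F_2", "G2F",
                        "G1FS1_1", "G1FS1_2", "G2FS1")

#' Construct a set of IgG Fc N-glycan peak heights
#'
#' Heights (arbitrary fluorescence units) of the seven main core-fucosylated
#' biantennary Fc N-glycan peaks of an APTS-labeled capillary
#' electropherogram: G0F (agalacto), the two G1F isomers (monogalacto), G2F
#' (digalacto), the two G1FS1 isomers (monogalacto-monosialo) and G2FS1
#' (digalacto-monosialo).
#'
#' @param G0F,G1F_1,G1F_2,G2F,G1FS1_1,G1FS1_2,G2FS1 non-negative peak
#'   heights.
#' @return Named numeric vector of class `glycan_peaks`.
#' @export
glycan_peaks <- function(G0F = 0, G1F_1 = 0, G1F_2 = 0, G2F = 0,
                         G1FS1_1 = 0, G1FS1_2 = 0, G2FS1 = 0) {
  p <- c(G0F = G0F, G1F_1 = G1F_1, G1F_2 = G1F_2, G2F = G2F,
         G1FS1_1 = G1FS1_1, G1FS1_2 = G1FS1_2, G2FS1 = G2FS1)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("peak heights must be finite and >= 0")
  }
  structure(p, class = "glycan_peaks")
}

.as_peaks <- function(peaks) {
  if (inherits(peaks, "glycan_peaks")) return(unclass(peaks))
  p <- unlist(peaks)
  missing <- setdiff(.glycan_peak_names, names(p))
  if (length(missing) > 0L) {
    stop("missing glycan peak(s): ", paste(missing, collapse = ", "))
  }
  p <- p[.glycan_peak_names]
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("peak heights must be finite and >= 0")
  }
  p
}

#' Relative IgG Fc sialylation
#'
#' Sialylated peak height over total peak height:
#' `(G2FS1 + G1FS1_1 + G1FS1_2) / sum of all seven peaks`. Scale-invariant.
#'
#' Note: with electrokinetic sample injection the extra negative charge of
#' sialylated glycans makes them load preferentially, so these relative
#' levels systematically overestimate true sialylation percentages; they are
#' comparable between samples but are not absolute occupancies, and no
#' correction factor is applied.
#'
#' @param peaks a [glycan_peaks()] (or named vector/list with the seven
#'   peaks).
#' @return Relative sialylation in `[0, 1]`.
#' @export
relative_sialylation <- function(peaks) {
  p <- .as_peaks(peaks)
  total <- sum(p)
  if (total <= 0) stop("all peak heights are zero; score undefined")
  unname((p[["G2FS1"]] + p[["G1FS1_1"]] + p[["G1FS1_2"]]) / total)
}

#' Undergalactosylation score (UGS)
#'
#' Weighted fraction of missing galactoses among the four neutral
#' (neuraminidase-digested) peaks:
#' `(G0F + 0.5*G1F_1 + 0.5*G1F_2) / (G0F + G1F_1 + G1F_2 + G2F)`.
#' 1 means fully agalactosylated, 0 fully digalactosylated. Intended for
#' profiles measured after sialidase digestion, so only the neutral peaks
#' enter; any sialylated peak heights present in the input are ignored.
#'
#' @inheritParams relative_sialylation
#' @return UGS in `[0, 1]`.
#' @export
undergalactosylation_score <- function(peaks) {
  p <- .as_peaks(peaks)
  denom <- p[["G0F"]] + p[["G1F_1"]] + p[["G1F_2"]] + p[["G2F"]]
  if (denom <= 0) stop("the four neutral peaks are all zero; UGS undefined")
  unname((p[["G0F"]] + 0.5 * p[["G1F_1"]] + 0.5 * p[["G1F_2"]]) / denom)
}

#' Construct transwell migration counts
#'
#' Cell and internal-control bead counts for a sample well and its control
#' well. Beads added in known amounts normalize away differences in acquired
#' volume between wells.
#'
#' @param migrated_cells_sample,migrated_cells_control migrated cell counts.
#' @param beads_sample,beads_control bead counts (> 0).
#' @return List of class `migration_counts`.
#' @export
migration_counts <- function(migrated_cells_sample, beads_sample,
                             migrated_cells_control, beads_control) {
  v <- c(migrated_cells_sample, beads_sample, migrated_cells_control,
         beads_control)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("counts must be finite and >= 0")
  }
  if (beads_sample <= 0 || beads_control <= 0) {
    stop("bead counts must be strictly positive")
  }
  structure(list(migrated_cells_sample = migrated_cells_sample,
                 beads_sample = beads_sample,
                 migrated_cells_control = migrated_cells_control,
                 beads_control = beads_control),
            class = "migration_counts")
}

#' Chemotaxis migration index
#'
#' Bead-normalized migration ratio of a sample well versus its control well:
#' `(migrated_cells_sample / beads_sample) /
#'  (migrated_cells_control / beads_control)`.
#'
#' @param counts a [migration_counts()] (or list with the four count
#'   fields).
#' @return Migration index (>= 0); errors if control migration is zero.
#' @export
migration_index <- function(counts) {
  if (!inherits(counts, "migration_counts")) {
    counts <- do.call(migration_counts, as.list(counts)[
      c("migrated_cells_sample", "beads_sample", "migrated_cells_control",
        "beads_control")])
  }
  if (counts$migrated_cells_control <= 0) {
    stop("no migrated cells in the control well; migration index undefined")
  }
  (counts$migrated_cells_sample / counts$beads_sample) /
    (counts$migrated_cells_control / counts$beads_control)
}

.read_table_arg <- function(x) {
  if (is.data.frame(x)) x else utils::read.csv(x, stringsAsFactors = FALSE)
}

.check_batch_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0L) {
    warning(what, ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
  }
  invisible(df)
}

#' Batch glycan scoring
#'
#' One row per sample with a `sample_id` column and one column per named
#' peak; computes relative sialylation and UGS per sample. Unknown columns
#' are ignored with a warning; missing required columns are an error.
#'
#' @param input a data.frame or CSV path with columns `sample_id` and the
#'   seven peaks `G0F, G1F_1, G1F_2, G2F, G1FS1_1, G1FS1_2, G2FS1`.
#' @param output optional CSV path for the scores.
#' @return data.frame with columns `sample_id`, `sialylation`, `ugs`.
#' @export
glyco_scores <- function(input, output = NULL) {
  df <- .read_table_arg(input)
  .check_batch_columns(df, c("sample_id", .glycan_peak_names), "glyco_scores")
  out <- data.frame(
    sample_id = df$sample_id,
    sialylation = vapply(seq_len(nrow(df)), function(i) {
      relative_sialylation(as.list(df[i, .glycan_peak_names]))
    }, numeric(1)),
    ugs = vapply(seq_len(nrow(df)), function(i) {
      undergalactosylation_score(as.list(df[i, .glycan_peak_names]))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(output)) utils::write.csv(out, output, row.names = FALSE)
  out
}

#' Batch migration indices
#'
#' @param input a data.frame or CSV path with columns `sample_id`,
#'   `migrated_cells_sample`, `beads_sample`, `migrated_cells_control`,
#'   `beads_control`.
#' @param output optional CSV path.
#' @return data.frame with columns `sample_id`, `migration_index`.
#' @export
migration_indices <- function(input, output = NULL) {
  df <- .read_table_arg(input)
  cols <- c("migrated_cells_sample", "beads_sample",
            "migrated_cells_control", "beads_control")
  .check_batch_columns(df, c("sample_id", cols), "migration_indices")
  out <- data.frame(
    sample_id = df$sample_id,
    migration_index = vapply(seq_len(nrow(df)), function(i) {
      migration_index(as.list(df[i, cols]))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(output)) utils::write.csv(out, output, row.names = FALSE)
  out
}
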