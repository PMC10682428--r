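#' Construct a Cq table
#'
#' A Cq table is a numeric matrix of quantification-cycle values with samples
#' in rows and assays (miRNAs) in columns. Missing reactions ("Undetermined"
#' wells) are `NA`, which is distinct from a Cq of 0. Values outside the
#' plausibility window \[0, 45\] are rejected unless `permissive = TRUE`:
#' Cq outside that range almost always indicates a unit or export error.
#'
#' @param values numeric matrix (samples x assays) or object coercible to one.
#' @param sample_ids,assay_ids identifiers; default to dimnames of `values`.
#' @param permissive allow Cq values outside \[0, 45\].
#' @return a `cq_table`: numeric matrix with class attribute and dimnames.
#' @export
cq_table <- function(values, sample_ids = rownames(values),
                     assay_ids = colnames(values), permissive = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(assay_ids)) {
    .stopf("cq_table needs sample and assay identifiers")
  }
  sample_ids <- as.character(sample_ids)
  assay_ids <- as.character(assay_ids)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(assay_ids)) {
    .stopf("dimensions (%d x %d) do not match id lists (%d samples, %d assays)",
           nrow(values), ncol(values), length(sample_ids), length(assay_ids))
  }
  if (anyDuplicated(sample_ids)) {
    .stopf("duplicated sample ids: %s",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(assay_ids)) {
    .stopf("duplicated assay ids: %s",
           paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "))
  }
  if (nrow(values) == 0L || ncol(values) == 0L) .stopf("empty Cq table")
  present <- values[!is.na(values)]
  if (any(!is.finite(present))) .stopf("non-finite Cq values present")
  if (!permissive && length(present) && any(present < 0 | present > 45)) {
    bad <- which(!is.na(values) & (values < 0 | values > 45), arr.ind = TRUE)[1L, ]
    .stopf("Cq value %.3g at (%s, %s) outside [0, 45]; use permissive = TRUE to keep",
           values[bad[1L], bad[2L]], sample_ids[bad[1L]], assay_ids[bad[2L]])
  }
  dimnames(values) <- list(sample_ids, assay_ids)
  structure(values, class = c("cq_table", "matrix", "array"))
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d samples x %d assays, %d missing\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x), 6L), ...)
  invisible(x)
}

#' Read a Cq table from delimited text
#'
#' Supports the two common export shapes: wide (`sample_id,<assay1>,...`, one
#' row per sample) and long (`sample_id,assay_id,cq` records). Tokens such as
#' `"Undetermined"` map to missing; they are never imputed to a maximum cycle.
#'
#' @param path file path; comma- or tab-delimited (sniffed from the header
#'   unless `sep` is given).
#' @param layout `"wide"` or `"long"`.
#' @param missing_tokens strings treated as missing Cq.
#' @param aggregate how to treat duplicate (sample, assay) records in long
#'   layout: `"error"` (default; technical replicates must be requested
#'   explicitly) or `"mean"`.
#' @param sep optional explicit delimiter (`","` or `"\t"`).
#' @param permissive passed to [cq_table()].
#' @return a [cq_table()].
#' @export
load_cq_table <- function(path, layout = c("wide", "long"),
                          missing_tokens = c("Undetermined", "NA", ""),
                          aggregate = c("error", "mean"),
                          sep = NULL, permissive = FALSE) {
  layout <- match.arg(layout)
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (nrow(df) == 0L) .stopf("empty table: %s", path)

  parse_cq <- function(x, where) {
    x[x %in% missing_tokens] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      .stopf("unparseable Cq value %s at %s", deparse(x[bad[1L]]), where[bad[1L]])
    }
    out
  }

  if (layout == "wide") {
    if (ncol(df) < 2L) .stopf("wide layout needs a sample id column plus assays")
    ids <- df[[1L]]
    assays <- colnames(df)[-1L]
    vals <- sapply(seq_along(assays), function(j) {
      parse_cq(df[[j + 1L]], sprintf("(row %s, column %s)", ids, assays[j]))
    })
    vals <- matrix(vals, nrow = length(ids), ncol = length(assays))
    cq_table(vals, ids, assays, permissive = permissive)
  } else {
    need <- c("sample_id", "assay_id", "cq")
    missing_cols <- setdiff(need, colnames(df))
    if (length(missing_cols)) {
      .stopf("long layout requires columns: %s (missing: %s)",
             paste(need, collapse = ", "), paste(missing_cols, collapse = ", "))
    }
    cqv <- parse_cq(df$cq, sprintf("(sample %s, assay %s)", df$sample_id, df$assay_id))
    key <- paste(df$sample_id, df$assay_id, sep = "\r")
    if (anyDuplicated(key)) {
      if (aggregate == "error") {
        d <- df[duplicated(key), , drop = FALSE]
        .stopf("duplicate records for (%s, %s); pass aggregate = \"mean\" to average replicates",
               d$sample_id[1L], d$assay_id[1L])
      }
      agg <- tapply(cqv, key, function(v) mean(v, na.rm = TRUE))
      agg[is.nan(agg)] <- NA_real_
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      cqv <- as.numeric(agg[paste(df$sample_id, df$assay_id, sep = "\r")])
    }
    ids <- unique(df$sample_id)
    assays <- unique(df$assay_id)
    vals <- matrix(NA_real_, length(ids), length(assays),
                   dimnames = list(ids, assays))
    vals[cbind(match(df$sample_id, ids), match(df$assay_id, assays))] <- cqv
    cq_table(vals, ids, assays, permissive = permissive)
  }
}

#' Write a Cq table to delimited text
#'
#' Inverse of [load_cq_table()]; a write/read round trip reproduces the table
#' exactly in either layout. Missing values are written as `Undetermined`.
#'
#' @param cq a [cq_table()].
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @export
write_cq_table <- function(cq, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(cq, "cq_table"))
  fmt <- function(v) ifelse(is.na(v), "Undetermined", formatC(v, digits = 17, format = "g"))
  if (layout == "wide") {
    df <- data.frame(sample_id = rownames(cq), check.names = FALSE)
    for (a in colnames(cq)) df[[a]] <- fmt(cq[, a])
  } else {
    df <- data.frame(
      sample_id = rep(rownames(cq), times = ncol(cq)),
      assay_id = rep(colnames(cq), each = nrow(cq)),
      cq = fmt(as.vector(cq))
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' One record per sample: diagnostic group, sex, age in years, and optional
#' batch/cohort labels. Unknown extra columns are preserved untouched.
#'
#' @param path delimited text with a header.
#' @param required columns that must be present.
#' @param sep optional explicit delimiter.
#' @return a data.frame with one row per sample, `age` numeric.
#' @export
load_metadata <- function(path, required = c("sample_id", "group", "sex", "age"),
                          sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    .stopf("metadata is missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    .stopf("duplicated sample_id in metadata: %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if ("age" %in% colnames(df)) {
    age <- suppressWarnings(as.numeric(df$age))
    bad <- which(!is.na(df$age) & df$age != "" & is.na(age))
    if (length(bad)) .stopf("non-numeric age %s for sample %s",
                            deparse(df$age[bad[1L]]), df$sample_id[bad[1L]])
    if (any(age < 0, na.rm = TRUE)) .stopf("negative age in metadata")
    df$age <- age
  }
  rownames(df) <- NULL
  df
}

#' Define the assay panel
#'
#' Declares which assays are candidate normalizers, which are exogenous
#' spike-in controls for the isolation and reverse-transcription stages, and
#' which pair drives the delta-Cq haemolysis rule. The candidate list is
#' capped at 11 by default: the combination search enumerates `2^n - 1`
#' subsets, which stays tractable up to that size.
#'
#' @param candidates ordered candidate-normalizer assay ids (determines
#'   combination codes).
#' @param spikein_isolation,spikein_rt spike-in assay ids per stage.
#' @param haemolysis_plasma_marker,haemolysis_rbc_marker delta-Cq marker pair.
#' @param allow_large lift the 11-candidate cap (cost doubles per candidate).
#' @return a `panel_config` list.
#' @export
panel_config <- function(candidates,
                         spikein_isolation = c("cel-miR-39-3p", "cel-miR-2-3p"),
                         spikein_rt = c("cel-miR-238-3p", "cel-miR-54-3p"),
                         haemolysis_plasma_marker = "hsa-miR-23a-3p",
                         haemolysis_rbc_marker = "hsa-miR-451a",
                         allow_large = FALSE) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) .stopf("candidate list is empty")
  if (anyDuplicated(candidates)) .stopf("duplicated candidate assay ids")
  if (length(candidates) > 11L && !allow_large) {
    .stopf("%d candidates exceed the supported panel size of 11 (2^n - 1 combinations); set allow_large = TRUE to override",
           length(candidates))
  }
  structure(list(candidates = candidates,
                 spikein_isolation = as.character(spikein_isolation),
                 spikein_rt = as.character(spikein_rt),
                 haemolysis_plasma_marker = haemolysis_plasma_marker,
                 haemolysis_rbc_marker = haemolysis_rbc_marker),
            class = "panel_config")
}

#' Read a panel configuration from YAML
#'
#' Keys mirror the arguments of [panel_config()]: `candidates` (required),
#' `spikein_isolation`, `spikein_rt`, `haemolysis_plasma_marker`,
#' `haemolysis_rbc_marker`.
#'
#' @param path YAML file.
#' @param allow_large passed to [panel_config()].
#' @export
load_panel_config <- function(path, allow_large = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$candidates)) .stopf("panel config must declare `candidates`")
  args <- cfg[intersect(names(cfg),
                        c("candidates", "spikein_isolation", "spikein_rt",
                          "haemolysis_plasma_marker", "haemolysis_rbc_marker"))]
  do.call(panel_config, c(args, list(allow_large = allow_large)))
}

#' Assemble an analysis-ready dataset
#'
#' Binds a Cq table, sample metadata and a panel configuration, checking that
#' they describe the same samples and that every panel assay is measured.
#'
#' @param cq a [cq_table()].
#' @param meta metadata data.frame with a `sample_id` column.
#' @param panel a [panel_config()].
#' @param mode `"strict"` requires the same sample set in `cq` and `meta`;
#'   `"lenient"` takes the intersection with a warning.
#' @return a `mirnorm_dataset` list with elements `cq`, `meta`, `panel`.
#' @export
assemble_dataset <- function(cq, meta, panel, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cq, "cq_table"), inherits(panel, "panel_config"))
  if (!"sample_id" %in% colnames(meta)) .stopf("metadata lacks sample_id")
  panel_assays <- unique(c(panel$candidates,
                           panel$haemolysis_plasma_marker, panel$haemolysis_rbc_marker))
  absent <- setdiff(panel$candidates, colnames(cq))
  if (length(absent)) {
    .stopf("panel assay(s) absent from the Cq table: %s",
           paste(absent, collapse = ", "))
  }
  common <- intersect(rownames(cq), meta$sample_id)
  if (length(common) == 0L) .stopf("no samples shared between Cq table and metadata")
  unmatched <- c(setdiff(rownames(cq), common), setdiff(meta$sample_id, common))
  if (length(unmatched)) {
    if (mode == "strict") {
      .stopf("samples without a match across Cq/metadata: %s (use mode = \"lenient\" to intersect)",
             paste(unmatched, collapse = ", "))
    }
    .warnf("dropping %d unmatched sample(s): %s", length(unmatched),
           paste(unmatched, collapse = ", "))
  }
  cq2 <- cq_table(unclass(cq)[common, , drop = FALSE], permissive = TRUE)
  meta2 <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  message(sprintf("assembled dataset: %d samples, %d assays (%d candidates)",
                  nrow(cq2), ncol(cq2), length(panel$candidates)))
  structure(list(cq = cq2, meta = meta2, panel = panel),
            class = "mirnorm_dataset")
}

#' @export
print.mirnorm_dataset <- function(x, ...) {
  cat(sprintf("<mirnorm_dataset> %d samples x %d assays; candidates: %s\n",
              nrow(x$cq), ncol(x$cq), paste(x$panel$candidates, collapse = ", ")))
  if ("group" %in% colnames(x$meta)) {
    print(table(x$meta$group))
  }
  invisible(x)
}

# sample -> group label lookup from a dataset
.dataset_groups <- function(dataset) {
  stats::setNames(as.character(dataset$meta$group), dataset$meta$sample_id)
}
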