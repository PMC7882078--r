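#' @useDynLib mirnetscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.evidence_sources <- c("miRTarBase", "TarBase", "miRecords", "miR2Disease",
                       "HOCTAR", "ExprTarget", "starBase")
.validated_sources <- c("miRTarBase", "TarBase", "miRecords", "miR2Disease")
.prediction_tools <- c("HOCTAR", "ExprTarget", "starBase")
.evidence_classes <- c("validated_low_throughput", "validated_high_throughput",
                       "predicted")

#' Load miRNA-target interaction evidence from a tab-separated table
#'
#' Each row is one interaction claim: a miRNA, a gene, the database it came
#' from, its evidence class, and the scores that database reports. Score
#' columns are only meaningful for the matching source (`hoctar_score`,
#' `exprtarget_score`, `starbase_readnum`, `starbase_bc`); they may be empty
#' (`NA`) elsewhere.
#'
#' @param path tab-separated file with header; mandatory columns `mirna`,
#'   `gene`, `source`, `evidence_class`. Score columns are optional and
#'   default to `NA`.
#' @return A data.frame of interaction evidence with one row per claim.
#' @export
load_interactions <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  mandatory <- c("mirna", "gene", "source", "evidence_class")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols) > 0) {
    stop("evidence table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_source <- which(!tab$source %in% .evidence_sources)
  if (length(bad_source) > 0) {
    stop(sprintf("unknown interaction source %s at row %d",
                 dQuote(tab$source[bad_source[1]]), bad_source[1]))
  }
  bad_class <- which(!tab$evidence_class %in% .evidence_classes)
  if (length(bad_class) > 0) {
    stop(sprintf("unknown evidence class %s at row %d",
                 dQuote(tab$evidence_class[bad_class[1]]), bad_class[1]))
  }
  for (col in c("hoctar_score", "exprtarget_score", "starbase_readnum",
                "starbase_bc")) {
    if (!col %in% names(tab)) {
      tab[[col]] <- NA_real_
    } else if (!is.numeric(tab[[col]])) {
      parsed <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(!is.na(tab[[col]]) & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value %s in column '%s' at row %d",
                     dQuote(tab[[col]][bad[1]]), col, bad[1]))
      }
      tab[[col]] <- parsed
    }
  }
  tab
}

#' Canonicalize a miRNA name
#'
#' Applies a user-supplied alias table (old name to current name, e.g. a
#' miRBase alias dump) when the name is listed there; otherwise the name is
#' returned unchanged apart from normalizing the case of the `hsa-miR-`
#' prefix. Arm suffixes (`-3p`/`-5p`) are never stripped.
#'
#' @param name character vector of miRNA names.
#' @param alias_table named character vector mapping aliases to canonical
#'   names; may be empty.
#' @return character vector of harmonized names.
#' @examples
#' harmonize_mirna_name("HSA-MIR-221-3P")
#' @export
harmonize_mirna_name <- function(name, alias_table = character()) {
  vapply(as.character(name), function(nm) {
    if (length(alias_table) > 0 && nm %in% names(alias_table)) {
      return(unname(alias_table[[nm]]))
    }
    if (grepl("^hsa-mir-", nm, ignore.case = TRUE)) {
      nm <- paste0("hsa-miR-", substring(nm, 9))
      # tail of the name (accession suffixes, arm labels) is lower-case in
      # canonical style
      nm <- paste0(substring(nm, 1, 8), tolower(substring(nm, 9)))
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}

#' Filtering thresholds for computationally predicted interactions
#'
#' @param hoctar_top_fraction keep the top fraction of HOCTAR pairs ranked
#'   by descending score (rank <= `ceiling(fraction * n)`, ties broken by
#'   lexicographic pair id).
#' @param exprtarget_min ExprTarget pairs pass when score is strictly over
#'   this value.
#' @param starbase_min_readnum,starbase_min_bc starBase pairs pass when
#'   read count and biological-complex count are both at least these values
#'   (inclusive).
#' @param min_tool_agreement a pair is accepted when it passes the filter of
#'   at least this many distinct prediction tools.
#' @return A list of class `prediction_filter_config`.
#' @export
prediction_filter_config <- function(hoctar_top_fraction = 0.5,
                                     exprtarget_min = 1,
                                     starbase_min_readnum = 10,
                                     starbase_min_bc = 2,
                                     min_tool_agreement = 2) {
  stopifnot(hoctar_top_fraction > 0, hoctar_top_fraction <= 1,
            starbase_min_readnum >= 0, starbase_min_bc >= 0,
            min_tool_agreement >= 1)
  structure(list(hoctar_top_fraction = hoctar_top_fraction,
                 exprtarget_min = exprtarget_min,
                 starbase_min_readnum = starbase_min_readnum,
                 starbase_min_bc = starbase_min_bc,
                 min_tool_agreement = min_tool_agreement),
            class = "prediction_filter_config")
}

.pair_id <- function(mirna, gene) paste(mirna, gene, sep = "\t")

#' Filter predicted interactions by per-tool thresholds and tool agreement
#'
#' A pair survives a tool's filter when that tool's record passes its
#' threshold: HOCTAR keeps the top fraction of pairs by descending score,
#' ExprTarget requires a score strictly over the cutoff, and starBase
#' requires both `readnum` and `bc` at or above their cutoffs. The returned
#' pairs are those passing at least `min_tool_agreement` distinct tools.
#'
#' @param evidence data.frame as returned by [load_interactions]; rows with
#'   non-prediction sources are ignored.
#' @param config a [prediction_filter_config].
#' @return data.frame with columns `mirna`, `gene`, one row per accepted
#'   pair, sorted by pair id.
#' @export
filter_predictions <- function(evidence,
                               config = prediction_filter_config()) {
  stopifnot(inherits(config, "prediction_filter_config"))
  pred <- evidence[evidence$source %in% .prediction_tools, , drop = FALSE]
  if (nrow(pred) == 0) {
    return(data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  pass <- list()

  hoc <- pred[pred$source == "HOCTAR" & !is.na(pred$hoctar_score), ]
  if (nrow(hoc) > 0) {
    ord <- order(-hoc$hoctar_score, .pair_id(hoc$mirna, hoc$gene))
    n_keep <- ceiling(config$hoctar_top_fraction * nrow(hoc))
    pass$HOCTAR <- .pair_id(hoc$mirna, hoc$gene)[ord][seq_len(n_keep)]
  }

  expr <- pred[pred$source == "ExprTarget" & !is.na(pred$exprtarget_score), ]
  pass$ExprTarget <- .pair_id(expr$mirna, expr$gene)[
    expr$exprtarget_score > config$exprtarget_min]

  star <- pred[pred$source == "starBase", ]
  ok <- !is.na(star$starbase_readnum) & !is.na(star$starbase_bc) &
    star$starbase_readnum >= config$starbase_min_readnum &
    star$starbase_bc >= config$starbase_min_bc
  pass$starBase <- .pair_id(star$mirna, star$gene)[ok]

  counts <- table(unlist(lapply(pass, unique)))
  keep <- sort(names(counts)[counts >= config$min_tool_agreement])
  parts <- strsplit(keep, "\t", fixed = TRUE)
  data.frame(mirna = vapply(parts, `[`, "", 1),
             gene = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Assemble the miRNA-mRNA reference network
#'
#' Combines experimentally validated interactions with filtered predicted
#' pairs. By default only validated records from low-throughput experiments
#' (e.g. qPCR, reporter assays) are trusted; high-throughput records are
#' included when `require_low_throughput = FALSE`. When the same pair
#' carries conflicting validated evidence classes the strongest class wins
#' and the conflict is reported as a message.
#'
#' @param validated data.frame of evidence rows with validated sources
#'   (other rows are ignored).
#' @param predicted_pairs data.frame with columns `mirna`, `gene` as
#'   returned by [filter_predictions].
#' @param require_low_throughput keep only low-throughput validated records
#'   (default `TRUE`).
#' @return A [regulatory_network].
#' @export
build_reference_network <- function(validated, predicted_pairs,
                                    require_low_throughput = TRUE) {
  val <- validated[validated$source %in% .validated_sources, , drop = FALSE]
  if (nrow(val) > 0) {
    id <- .pair_id(val$mirna, val$gene)
    cls <- split(val$evidence_class, id)
    n_conflict <- sum(vapply(cls, function(x) length(unique(x)) > 1,
                             logical(1)))
    if (n_conflict > 0) {
      message(n_conflict,
              " pair(s) with conflicting evidence classes; keeping the ",
              "strongest class per pair")
    }
    # strongest class per pair, by the order of .evidence_classes
    best <- vapply(cls, function(x) {
      .evidence_classes[min(match(x, .evidence_classes))]
    }, character(1))
    if (require_low_throughput) {
      best <- best[best == "validated_low_throughput"]
    }
    keep_ids <- names(best)
  } else {
    keep_ids <- character()
  }
  all_ids <- union(keep_ids, .pair_id(predicted_pairs$mirna,
                                      predicted_pairs$gene))
  parts <- strsplit(sort(all_ids), "\t", fixed = TRUE)
  regulatory_network(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
}
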