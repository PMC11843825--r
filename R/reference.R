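# Healing-time clinical reference classification. Burn class is assigned
# from the time to spontaneous wound closure (or surgical treatment), on day
# 3-4 when a steady state is reached, and then retrospectively propagated to
# days 0-3. Full-thickness (class 3) wounds cannot arise from healing times
# alone (all surgical/deep wounds map to 2b2); they enter only through an
# explicit clinical annotation flag.

#' Classify a healing record into a burn class
#'
#' Spontaneous closure by day 14 is class 2a; closure on days 15-21 is 2b1;
#' closure after day 21, or any surgical treatment, is 2b2. A
#' \code{clinical_grade3} annotation forces class 3. Boundary days are
#' config-exposed via \code{d2a} (last day counted as 2a, default 14) and
#' \code{d2b1} (last day counted as 2b1, default 21).
#'
#' @param closure_day integer day of spontaneous closure, or NA.
#' @param surgical logical surgical-treatment flag.
#' @param clinical_grade3 logical full-thickness annotation.
#' @param d2a,d2b1 class boundary days (inclusive).
#' @return a burn class label (see [burnClasses()]). Vectorized.
#' @export
classifyHealing <- function(closure_day, surgical = FALSE,
                            clinical_grade3 = FALSE, d2a = 14L, d2b1 = 21L) {
  n <- max(length(closure_day), length(surgical), length(clinical_grade3))
  closure_day <- rep_len(closure_day, n)
  surgical <- rep_len(surgical, n)
  clinical_grade3 <- rep_len(clinical_grade3, n)
  incomplete <- is.na(closure_day) & !surgical & !clinical_grade3
  if (any(incomplete)) {
    stopDegenerate("incomplete healing record: neither closure_day nor surgical/grade-3 flag")
  }
  if (any(closure_day < 0, na.rm = TRUE)) {
    stopDegenerate("closure_day must be >= 0")
  }
  out <- ifelse(clinical_grade3, "3",
         ifelse(surgical, "2b2",
         ifelse(closure_day <= d2a, "2a",
         ifelse(closure_day <= d2b1, "2b1", "2b2"))))
  out
}

#' Retrospectively assign segment classes to days 0-3
#'
#' Each segment carries a single reference class which is constant across all
#' days it was observed; this expands a per-segment class table onto the
#' per-day observation table.
#'
#' @param observations data.frame with columns \code{segment_id, day}.
#' @param class_by_segment data.frame with columns \code{segment_id, class};
#'   one class per segment (conflicting duplicates are an error).
#' @return the observation table with a \code{class} column added.
#' @export
assignRetrospective <- function(observations, class_by_segment) {
  agg <- unique(class_by_segment[c("segment_id", "class")])
  dup <- agg$segment_id[duplicated(agg$segment_id)]
  if (length(dup)) {
    stopDegenerate(paste("conflicting classes for segment(s):",
                         paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(observations$segment_id, agg$segment_id)
  if (length(missing)) {
    stopDegenerate(paste("no class for segment(s):", paste(missing, collapse = ", ")))
  }
  out <- merge(observations, agg, by = "segment_id", sort = FALSE)
  out[order(out$segment_id, out$day), , drop = FALSE]
}

#' Read a healing-outcome table
#'
#' CSV with columns \code{segment_id,closure_day,surgical,clinical_grade3}
#' (\code{closure_day} may be empty for surgical records).
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
readHealingCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "closure_day", "surgical", "clinical_grade3")
  if (!all(need %in% names(tab))) {
    stopDegenerate("healing CSV must have columns segment_id,closure_day,surgical,clinical_grade3")
  }
  tab$closure_day <- suppressWarnings(as.integer(tab$closure_day))
  tab$surgical <- as.logical(tab$surgical)
  tab$clinical_grade3 <- as.logical(tab$clinical_grade3)
  tab
}

#' @rdname readHealingCsv
#' @param tab healing data.frame.
#' @export
writeHealingCsv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
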