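#' Improvement typology codes
#'
#' The seven distinct types of agricultural-productivity improvement:
#' elementary (EI), stability (SI), potential (PI), intensity (II),
#' stability+potential (SPI), stability+intensity (SII) and optimal (OI)
#' improvement.
#' @return character vector of the seven type codes.
#' @export
improvement_types <- function() c("EI", "SI", "PI", "II", "SPI", "SII", "OI")

# Required flag pattern (pl, pv, pp, mi) per type. In inclusive mode a type
# holds when its required flags hold; in exclusive mode the remaining flags
# must be non-effective (the literal published table rows).
.type_requirements <- list(
  EI  = c(pl = TRUE, pv = FALSE, pp = FALSE, mi = FALSE),
  SI  = c(pl = TRUE, pv = TRUE,  pp = FALSE, mi = FALSE),
  PI  = c(pl = TRUE, pv = FALSE, pp = TRUE,  mi = FALSE),
  II  = c(pl = TRUE, pv = FALSE, pp = FALSE, mi = TRUE),
  SPI = c(pl = TRUE, pv = TRUE,  pp = TRUE,  mi = FALSE),
  SII = c(pl = TRUE, pv = TRUE,  pp = FALSE, mi = TRUE),
  OI  = c(pl = TRUE, pv = TRUE,  pp = TRUE,  mi = TRUE))

#' Assign improvement types from the four effectiveness flags
#'
#' Maps a project's four effectiveness flags (upgraded productivity level,
#' reduced productivity variation, improved productivity potential,
#' increased multi-cropping index) to the seven improvement types.
#'
#' Two readings of the published type table are supported. The default
#' `"inclusive"` mode treats each row as "at least these indicators
#' effective", which makes the types a lattice (OI implies SPI and SII;
#' SPI implies SI and PI; SII implies SI and II; any type implies EI) and
#' makes the EI rate of a cohort equal its upgraded-PL rate — the identity
#' the published national rates satisfy. The `"exclusive"` mode takes the
#' rows literally (listed non-required indicators must be non-effective),
#' under which the seven types partition the PL-effective projects except
#' for one combination absent from the table (PL and PP and MI without
#' PV), reported as `UNMAPPED` rather than silently merged.
#'
#' @param flags logical vector or one-row data.frame with elements
#'   `effective_pl`, `effective_pv`, `effective_pp`, `effective_mi` (or
#'   unnamed in that order).
#' @param mode `"inclusive"` (default) or `"exclusive"`.
#' @return list with `memberships` (named logical over the seven types)
#'   and `exclusive_label` (one type code, `"NONE"` when PL is
#'   non-effective, or `"UNMAPPED"`).
#' @export
assign_types <- function(flags, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  if (is.data.frame(flags) || is.list(flags))
    flags <- unlist(flags[c("effective_pl", "effective_pv",
                            "effective_pp", "effective_mi")])
  if (length(flags) != 4 || !is.logical(flags))
    stop("`flags` must supply four logical effectiveness values")
  names(flags) <- c("pl", "pv", "pp", "mi")

  exact <- vapply(.type_requirements, function(req) all(flags == req), logical(1))
  exclusive_label <- if (!flags[["pl"]]) "NONE"
                     else if (any(exact)) names(exact)[exact]
                     else "UNMAPPED"
  memberships <- if (mode == "inclusive") {
    vapply(.type_requirements, function(req) all(flags[req]), logical(1))
  } else {
    stats::setNames(improvement_types() == exclusive_label, improvement_types())
  }
  list(memberships = memberships, exclusive_label = exclusive_label)
}

#' Type every project of an indicator table
#'
#' Vectorized [assign_types()] over a per-project indicator table.
#'
#' @param indicators data.frame with the four `effective_*` flag columns
#'   (as produced by [evaluate_project()] / [evaluate_cohort_series()]).
#' @param mode passed to [assign_types()].
#' @return the input with seven logical membership columns (`EI` ... `OI`)
#'   and an `exclusive_label` column appended.
#' @export
assign_types_cohort <- function(indicators, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  res <- lapply(seq_len(nrow(indicators)), function(i)
    assign_types(indicators[i, ], mode = mode))
  mem <- do.call(rbind, lapply(res, function(r) as.data.frame(as.list(r$memberships))))
  out <- cbind(indicators, mem)
  out$exclusive_label <- vapply(res, `[[`, character(1), "exclusive_label")
  out
}
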