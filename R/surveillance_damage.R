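# Fruit-level damage attribution and surveillance summaries.
#
# Sap-beetle (Carpophilus) and moth damage in walnuts is discriminated by
# live stages and, failing those, by the diagnostic traces: silk threads and
# coarse frass (> 0.5 mm diameter) indicate moths; fine frass (<= 0.1 mm,
# kernel residue and excrement) indicates sap beetles.

FRUIT_CATEGORIES <- c("sorted", "unsorted", "discarded", "ground")

#' Validate fruit inspection records
#'
#' @param df A data.frame with columns `fruit_id`, `site_id`, `year`,
#'   `category` (`sorted`/`unsorted`/`discarded`/`ground`),
#'   `sap_beetle_adults`, `sap_beetle_larvae` (counts >= 0),
#'   `moth_stages_present`, `silk_threads` (logical), `frass_diameter_mm`
#'   (`NA` when no frass was observed), `kernel_damaged`, `sheath_crack`
#'   (logical).
#' @return The validated data.frame, classed `fruit_records`.
#' @export
fruit_records <- function(df) {
  req <- c("fruit_id", "site_id", "year", "category", "sap_beetle_adults",
           "sap_beetle_larvae", "moth_stages_present", "silk_threads",
           "frass_diameter_mm", "kernel_damaged", "sheath_crack")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing fruit-record columns: ", paste(miss, collapse = ", "))
  if (any(df$sap_beetle_adults < 0) || any(df$sap_beetle_larvae < 0))
    stop("negative insect counts")
  bad <- setdiff(unique(df$category), FRUIT_CATEGORIES)
  if (length(bad))
    stop("unknown fruit category: ", paste(bad, collapse = ", "))
  if (any(!is.na(df$frass_diameter_mm) & df$frass_diameter_mm < 0))
    stop("negative frass diameter")
  for (col in c("moth_stages_present", "silk_threads", "kernel_damaged",
                "sheath_crack"))
    if (!is.logical(df[[col]])) stop(col, " must be logical")
  class(df) <- c("fruit_records", class(df))
  df
}

#' Attribute the damage in each inspected fruit
#'
#' Applies the attribution clauses in fixed precedence:
#' \enumerate{
#'   \item live sap-beetle stages and live moth stages: `both`;
#'   \item live sap-beetle stages (adults or larvae): `sap_beetle`;
#'   \item live moth stages: `moth`;
#'   \item no live insects but silk threads or frass > 0.5 mm: `moth`;
#'   \item frass present and <= 0.1 mm: `sap_beetle`;
#'   \item frass in (0.1, 0.5\] mm without silk: `undetermined` (no stated
#'     rule covers this gap; nothing is silently attributed);
#'   \item no evidence at all: `none`.
#' }
#'
#' @param records A [fruit_records()] data.frame.
#' @return The records with columns `label` (one of `sap_beetle`, `moth`,
#'   `both`, `none`, `undetermined`) and `rule_fired` appended.
#' @export
classify_damage <- function(records) {
  records <- fruit_records(as.data.frame(records))
  sap_live <- records$sap_beetle_adults + records$sap_beetle_larvae > 0
  moth_live <- records$moth_stages_present
  frass <- records$frass_diameter_mm
  has_frass <- !is.na(frass)
  silk <- records$silk_threads

  label <- rep("none", nrow(records))
  rule <- rep("no_evidence", nrow(records))

  set <- function(cond, lab, r) {
    hit <- cond & label == "none" & rule == "no_evidence"
    label[hit] <<- lab; rule[hit] <<- r
  }
  set(sap_live & moth_live, "both", "live_sap_beetle_and_moth")
  set(sap_live, "sap_beetle", "live_sap_beetle")
  set(moth_live, "moth", "live_moth")
  set(silk | (has_frass & frass > 0.5), "moth", "silk_or_coarse_frass")
  set(has_frass & frass <= 0.1, "sap_beetle", "fine_frass")
  set(has_frass & frass > 0.1 & frass <= 0.5, "undetermined",
      "intermediate_frass")

  records$label <- label
  records$rule_fired <- rule
  records
}

#' Site-level infestation summary
#'
#' A site counts as infested when at least one of its fruits is attributed
#' to the sap beetle (`sap_beetle` or `both`). Percentages are reported
#' both truncated and rounded to one decimal; surveillance reports in this
#' system print the truncated figure (10/18 prints as 55.5%).
#'
#' @param records A [fruit_records()] data.frame (classified on the fly if
#'   `label` is absent).
#' @param sites Optional data.frame `site_id`, `site_type` enabling a
#'   per-site-type breakdown.
#' @return A list with `by_year` (data.frame: `year`, `n_sites`,
#'   `n_infested`, `percent_truncated`, `percent_rounded`) and, when
#'   `sites` is given, `by_site_type` (the same per year and site type).
#' @export
site_infestation_summary <- function(records, sites = NULL) {
  if (!"label" %in% names(records)) records <- classify_damage(records)
  infested_labels <- c("sap_beetle", "both")
  site_year <- unique(records[, c("site_id", "year")])
  site_year$infested <- mapply(function(s, y) {
    any(records$label[records$site_id == s & records$year == y] %in%
          infested_labels)
  }, site_year$site_id, site_year$year)

  summarise <- function(d) {
    n <- nrow(d); ni <- sum(d$infested)
    pct <- if (n > 0) 100 * ni / n else 0
    data.frame(n_sites = n, n_infested = ni,
               percent_truncated = percent_format(pct, 1, "truncate"),
               percent_rounded = percent_format(pct, 1, "round"))
  }
  by_year <- do.call(rbind, lapply(split(site_year, site_year$year),
                                   function(d) cbind(year = d$year[1],
                                                     summarise(d))))
  rownames(by_year) <- NULL
  out <- list(by_year = by_year)

  if (!is.null(sites)) {
    st <- merge(site_year, sites[, c("site_id", "site_type")],
                by = "site_id", all.x = TRUE)
    parts <- split(st, list(st$year, st$site_type), drop = TRUE)
    by_type <- do.call(rbind, lapply(parts, function(d)
      cbind(year = d$year[1], site_type = d$site_type[1], summarise(d))))
    rownames(by_type) <- NULL
    out$by_site_type <- by_type
  }
  out
}

#' Per-category damage and beetle-load table
#'
#' For each walnut category (and year, when several are present): the
#' percentage of fruits damaged by the sap beetle, computed per site and
#' aggregated as mean +/- SE (SE = SD / sqrt(n_sites)) with the min-max
#' range across sites; and the sap-beetle load (adults + larvae) per
#' infested walnut, mean +/- SE and range over infested fruits only.
#'
#' @param records A [fruit_records()] data.frame (classified on the fly if
#'   needed).
#' @return A data.frame with one row per year x category.
#' @export
category_damage_table <- function(records) {
  if (!"label" %in% names(records)) records <- classify_damage(records)
  damaged <- records$label %in% c("sap_beetle", "both")
  beetles <- records$sap_beetle_adults + records$sap_beetle_larvae

  parts <- split(seq_len(nrow(records)),
                 list(records$year, records$category), drop = TRUE)
  rows <- lapply(parts, function(idx) {
    d <- records[idx, ]
    dmg <- damaged[idx]
    site_pct <- 100 * tapply(dmg, d$site_id, mean)
    ns <- length(site_pct)
    inf <- beetles[idx][dmg & beetles[idx] > 0]
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    data.frame(
      year = d$year[1], category = d$category[1],
      n_sites = ns, n_fruits = nrow(d),
      pct_damaged_mean = mean(site_pct),
      pct_damaged_se = se(as.numeric(site_pct)),
      pct_damaged_min = min(site_pct), pct_damaged_max = max(site_pct),
      beetles_per_walnut_mean = if (length(inf)) mean(inf) else NA_real_,
      beetles_per_walnut_se = if (length(inf)) se(inf) else NA_real_,
      beetles_per_walnut_min = if (length(inf)) min(inf) else NA_real_,
      beetles_per_walnut_max = if (length(inf)) max(inf) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$year, match(out$category, FRUIT_CATEGORIES)), ]
}
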