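#' Read claims-like records from delimited text
#'
#' Reads a CSV/TSV of claims with a header row. `column_map` renames source
#' columns onto the canonical record fields: `person_key`, `incurred_date`,
#' `zip`, `age_years`, `gender`, `race`, `hispanic`, `payer_lob`, and either
#' `dx_code` or a logical `refusal` flag.
#'
#' @param path file path.
#' @param column_map named character vector `canonical = source`, optional.
#' @param sep field separator (default `,`).
#' @return A data frame of claim records.
#' @export
read_claims <- function(path, column_map = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(column_map)) {
    idx <- match(column_map, names(df))
    assert_that(!anyNA(idx), "column_map references absent columns")
    names(df)[idx] <- names(column_map)
  }
  if ("age_years" %in% names(df)) df$age_years <- as.integer(df$age_years)
  if ("refusal" %in% names(df))
    df$refusal <- as.logical(as.integer(df$refusal))
  validate_claims(df)
  df
}

validate_claims <- function(records) {
  need <- c("person_key", "incurred_date", "zip", "age_years")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("claims records missing field(s): %s", paste(miss, collapse = ", "))
  assert_that(all(nzchar(records$zip)), "empty ZIP in claims records")
  assert_that(all(records$age_years >= 0, na.rm = TRUE),
              "negative age in claims records")
  d <- as.Date(records$incurred_date)
  assert_that(!anyNA(d) || !nrow(records), "unparseable incurred_date")
  invisible(records)
}

#' Keep claims of young children
#'
#' Retains exactly the records with `age_years <= max_age` (age at date of
#' service; "six or below" is inclusive), preserving input order.
#'
#' @param records claims data frame.
#' @param max_age inclusive age ceiling in years (default 6).
#' @return The filtered records.
#' @export
filter_child_claims <- function(records, max_age = 6) {
  assert_that(max_age >= 0, "max_age must be nonnegative")
  records[records$age_years <= max_age, , drop = FALSE]
}

#' Flag vaccine-refusal claims
#'
#' A claim indicates refusal if its ICD-10-CM diagnosis code is in the Z28
#' family ("Immunization not carried out and underimmunization status") —
#' any subcode, case-insensitive — or if an explicit logical `refusal`
#' column is set. Errors if the records carry neither field.
#'
#' @param records claims data frame with `dx_code` and/or `refusal`.
#' @return Logical vector, one element per record.
#' @export
flag_refusal <- function(records) {
  has_dx <- "dx_code" %in% names(records)
  has_flag <- "refusal" %in% names(records)
  if (!has_dx && !has_flag)
    stop("records carry neither a dx_code nor a refusal flag")
  out <- rep(FALSE, nrow(records))
  if (has_dx)
    out <- out | startsWith(toupper(trimws(records$dx_code)), "Z28")
  if (has_flag)
    out <- out | (!is.na(records$refusal) & records$refusal)
  out
}

#' Feature schema for quarterly aggregation
#'
#' Fixes the category -> one-hot-column mapping used by
#' [aggregate_quarterly()]. Missing or unrecognised categories are mapped
#' to an explicit `"unknown"` level rather than dropped.
#'
#' @param gender,race,hispanic,payer_lob character vectors of category
#'   levels for each demographic field.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(gender = c("F", "M", "unknown"),
                           race = c("black", "other", "white", "unknown"),
                           hispanic = c("yes", "no", "unknown"),
                           payer_lob = c("commercial", "medicaid",
                                         "medicare", "unknown")) {
  fields <- list(gender = gender, race = race, hispanic = hispanic,
                 payer_lob = payer_lob)
  structure(list(fields = fields), class = "feature_schema")
}

schema_from_records <- function(records) {
  lv <- function(f)
    sort(unique(c(tolower(trimws(records[[f]])), "unknown")))
  feature_schema(gender = lv("gender"), race = lv("race"),
                 hispanic = lv("hispanic"), payer_lob = lv("payer_lob"))
}

schema_feature_names <- function(schema) {
  c(unlist(lapply(names(schema$fields), function(f)
    paste(f, schema$fields[[f]], sep = ".")), use.names = FALSE), "total")
}

#' Aggregate child claims into a quarterly ZIP panel
#'
#' For every ZIP i and calendar quarter t: `p[i, t]` is the number of
#' unique children with at least one claim; the feature columns are
#' unique-children counts per one-hot demographic category (gender, race,
#' Hispanic indicator, payer line of business) plus the total unique-child
#' count; and `h[i, t]` is the fraction of those unique children with at
#' least one refusal-flagged claim in the quarter. Counting is always of
#' unique children, never of claims. Cells with `p = 0` get `h = 0` and are
#' masked out.
#'
#' @param records claims data frame, already filtered to children
#'   (see [filter_child_claims()]).
#' @param schema a [feature_schema()]; derived from the data when `NULL`.
#' @param zips_keep ordered ZIP vector defining the panel rows; defaults to
#'   the sorted ZIPs present in `records`.
#' @return A raw (unnormalized) [node_panel()].
#' @export
aggregate_quarterly <- function(records, schema = NULL, zips_keep = NULL) {
  validate_claims(records)
  if (is.null(zips_keep)) zips_keep <- sort(unique(records$zip))
  zips_keep <- as.character(zips_keep)
  records <- records[records$zip %in% zips_keep, , drop = FALSE]
  if (!nrow(records)) stop("no claims fall in any kept ZIP")
  if (is.null(schema)) schema <- schema_from_records(records)

  q <- quarter_label(records$incurred_date)
  quarters <- quarter_seq(min(q), max(q))
  N <- length(zips_keep); TS <- length(quarters)
  fnames <- schema_feature_names(schema)
  X <- length(fnames)

  refusal <- flag_refusal(records)
  zi <- match(records$zip, zips_keep)
  ti <- match(q, quarters)

  ## one row per unique (zip, quarter, child)
  key <- paste(zi, ti, records$person_key, sep = "\r")
  first <- !duplicated(key)
  child_zi <- zi[first]; child_ti <- ti[first]
  ## a child counts as refusing if any of its claims this quarter is flagged
  refused <- as.logical(stats::ave(refusal + 0, key, FUN = max))[first]

  p <- matrix(0L, N, TS)
  tab <- table(factor(child_zi, levels = seq_len(N)),
               factor(child_ti, levels = seq_len(TS)))
  p[] <- as.integer(tab)
  refusers <- matrix(0L, N, TS)
  rt <- table(factor(child_zi[refused], levels = seq_len(N)),
              factor(child_ti[refused], levels = seq_len(TS)))
  refusers[] <- as.integer(rt)
  h <- ifelse(p > 0, refusers / pmax(p, 1L), 0)

  nc <- array(0, c(N, X, TS))
  crec <- records[first, , drop = FALSE]
  col <- 0L
  for (f in names(schema$fields)) {
    lev <- schema$fields[[f]]
    ## category matching is case-insensitive; unmapped values -> unknown
    v <- lev[match(tolower(trimws(crec[[f]])), tolower(lev))]
    v[is.na(v)] <- "unknown"
    for (l in lev) {
      col <- col + 1L
      sel <- v == l
      if (any(sel)) {
        cnt <- table(factor(child_zi[sel], levels = seq_len(N)),
                     factor(child_ti[sel], levels = seq_len(TS)))
        nc[, col, ] <- as.integer(cnt)
      }
    }
  }
  nc[, X, ] <- p  # total unique children

  node_panel(zips_keep, quarters, nc, h, p, fnames)
}
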