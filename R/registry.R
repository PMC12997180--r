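# Model provenance registry: who each ensemble member is, where it comes from,
# and what it costs. Provenance is mandatory data, not an afterthought: every
# downstream attribution groups models by these fields.

dx_regions <- c("US", "Europe", "China", "Other")
dx_cost_tiers <- c("free", "paid")
dx_parameter_classes <- c("small", "medium", "large")

dx_registry_columns <- c(
  "model_id", "provider", "origin_region", "cost_tier", "release_date",
  "parameter_class", "architecture_family", "intended_scope"
)

# Country/area -> region bucket lookup for free-text origin values.
# Unmapped values fall back to "Other" with a warning.
dx_region_lookup <- c(
  "us" = "US", "usa" = "US", "united states" = "US",
  "united states of america" = "US", "u.s." = "US", "u.s.a." = "US",
  "canada" = "Other",
  "uk" = "Europe", "united kingdom" = "Europe", "england" = "Europe",
  "france" = "Europe", "germany" = "Europe", "sweden" = "Europe",
  "norway" = "Europe", "finland" = "Europe", "denmark" = "Europe",
  "netherlands" = "Europe", "spain" = "Europe", "italy" = "Europe",
  "switzerland" = "Europe", "poland" = "Europe", "ireland" = "Europe",
  "europe" = "Europe", "eu" = "Europe",
  "china" = "China", "prc" = "China", "people's republic of china" = "China",
  "israel" = "Other", "japan" = "Other", "south korea" = "Other",
  "korea" = "Other", "india" = "Other", "singapore" = "Other",
  "australia" = "Other", "uae" = "Other", "russia" = "Other",
  "brazil" = "Other", "other" = "Other"
)

new_registry <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("dx_registry", "data.frame"))
}

#' Load a model provenance registry
#'
#' Reads an ordered collection of model profiles from YAML (a list of
#' mappings) or CSV (header row `model_id,provider,origin_region,cost_tier,
#' release_date,parameter_class,architecture_family,intended_scope`).
#' Profiles are validated on load: `model_id` must be unique, `cost_tier`
#' and `parameter_class` must come from their closed vocabularies, and
#' `origin_region` is normalized to the four region buckets
#' (US / Europe / China / Other). Free-text countries are mapped through a
#' shipped lookup table; anything unmapped becomes `"Other"` with a warning.
#' Missing optional fields never fail validation -- they form an
#' `"unknown"` group when the registry is grouped.
#'
#' @param path Path to the registry file.
#' @param format `"auto"` (by extension), `"yaml"`, or `"csv"`.
#' @return A `dx_registry` data frame, one row per model, file order
#'   preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("model_id,provider,origin_region,cost_tier",
#'              "m1,acme,US,free", "m2,acme,Europe,paid"), tf)
#' load_registry(tf)
load_registry <- function(path, format = c("auto", "yaml", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_validation(sprintf("registry file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  rows <- if (format == "yaml") {
    docs <- yaml::read_yaml(path)
    if (is.null(docs)) list() else docs
  } else {
    txt <- readLines(path, warn = FALSE)
    if (length(txt) <= 1L && !nzchar(paste(txt, collapse = ""))) {
      list()
    } else {
      df <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE, strip.white = TRUE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    }
  }
  if (length(rows) == 0L) {
    warning("registry file is empty; returning an empty registry")
    df <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(dx_registry_columns)),
                      dx_registry_columns),
      stringsAsFactors = FALSE
    )
    return(new_registry(df))
  }
  profiles <- lapply(seq_along(rows), function(i) {
    validate_profile(rows[[i]], row_idx = i)
  })
  df <- do.call(rbind, lapply(profiles, as.data.frame,
                              stringsAsFactors = FALSE))
  dup <- df$model_id[duplicated(df$model_id)]
  if (length(dup) > 0L) {
    stop_validation(sprintf("duplicate model_id in registry: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  message(sprintf("loaded registry with %d model profile(s)", nrow(df)))
  new_registry(df)
}

validate_profile <- function(row, row_idx = NA_integer_) {
  # NULL/"" both count as missing for optional fields
  get <- function(field) {
    v <- row[[field]]
    if (is.null(v) || length(v) == 0L || is.na(v) || !nzchar(as.character(v))) {
      NA_character_
    } else {
      as.character(v)
    }
  }
  model_id <- get("model_id")
  if (is.na(model_id)) {
    stop_validation(sprintf("row %s: missing required field 'model_id'",
                            row_idx))
  }
  region <- get("origin_region")
  if (is.na(region)) {
    stop_validation(sprintf("row %s (%s): missing required field 'origin_region'",
                            row_idx, model_id))
  }
  if (!region %in% dx_regions) {
    mapped <- dx_region_lookup[tolower(trimws(region))]
    if (is.na(mapped)) {
      warning(sprintf("row %s (%s): unmapped origin_region '%s' assigned to 'Other'",
                      row_idx, model_id, region))
      region <- "Other"
    } else {
      region <- unname(mapped)
    }
  }
  tier <- get("cost_tier")
  if (is.na(tier)) {
    stop_validation(sprintf("row %s (%s): missing required field 'cost_tier'",
                            row_idx, model_id))
  }
  tier <- tolower(trimws(tier))
  if (!tier %in% dx_cost_tiers) {
    stop_validation(sprintf("row %s (%s): unknown cost_tier token '%s' (valid: %s)",
                            row_idx, model_id, row[["cost_tier"]],
                            paste(dx_cost_tiers, collapse = ", ")))
  }
  pclass <- get("parameter_class")
  if (!is.na(pclass)) {
    pclass <- tolower(trimws(pclass))
    if (!pclass %in% dx_parameter_classes) {
      stop_validation(sprintf(
        "row %s (%s): unknown parameter_class token '%s' (valid: %s)",
        row_idx, model_id, row[["parameter_class"]],
        paste(dx_parameter_classes, collapse = ", ")))
    }
  }
  rdate <- get("release_date")
  if (!is.na(rdate)) {
    parsed <- tryCatch(as.Date(rdate), error = function(e) NA)
    if (is.na(parsed)) {
      stop_validation(sprintf("row %s (%s): release_date '%s' is not an ISO-8601 date",
                              row_idx, model_id, rdate))
    }
    rdate <- format(parsed)
  }
  list(model_id = model_id, provider = get("provider"),
       origin_region = region, cost_tier = tier, release_date = rdate,
       parameter_class = pclass,
       architecture_family = get("architecture_family"),
       intended_scope = get("intended_scope"))
}

#' Write a registry back to disk
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(r, f))`
#' is the identity on validated registries.
#'
#' @param registry A `dx_registry`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"yaml"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, format = c("auto", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  df <- as.data.frame(registry, stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      r[!vapply(r, function(v) is.na(v), logical(1))]
    })
    yaml::write_yaml(rows, path)
  }
  invisible(path)
}

#' Group a registry along a provenance axis
#'
#' Tallies registry members along one of the registered grouping axes.
#' Profiles missing an optional axis value fall into group `"unknown"`.
#' Counts always sum to the registry size and shares to 1.
#'
#' @param registry A `dx_registry`.
#' @param axis One of `"origin_region"`, `"cost_tier"`, `"parameter_class"`.
#' @return A data frame with columns `group`, `n`, `share`, and a
#'   list-column `members` of model ids.
#' @export
group_by_axis <- function(registry,
                          axis = c("origin_region", "cost_tier",
                                   "parameter_class")) {
  valid <- c("origin_region", "cost_tier", "parameter_class")
  if (length(axis) == 1L && !axis %in% valid) {
    stop_validation(sprintf("unknown grouping axis '%s' (valid axes: %s)",
                            axis, paste(valid, collapse = ", ")))
  }
  axis <- match.arg(axis)
  vals <- registry[[axis]]
  vals[is.na(vals)] <- "unknown"
  vocab <- switch(axis,
                  origin_region = dx_regions,
                  cost_tier = dx_cost_tiers,
                  parameter_class = dx_parameter_classes)
  levels <- c(vocab[vocab %in% vals], setdiff(unique(vals), vocab))
  n_total <- nrow(registry)
  out <- data.frame(group = levels, n = NA_integer_, share = NA_real_,
                    stringsAsFactors = FALSE)
  out$members <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    sel <- vals == levels[i]
    out$n[i] <- sum(sel)
    out$share[i] <- if (n_total > 0L) sum(sel) / n_total else NA_real_
    out$members[[i]] <- registry$model_id[sel]
  }
  out
}

#' @export
print.dx_registry <- function(x, ...) {
  cat(sprintf("<dx_registry> %d model profile(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    g <- group_by_axis(x, "origin_region")
    cat("  regions:",
        paste(sprintf("%s %d (%.1f%%)", g$group, g$n, 100 * g$share),
              collapse = ", "), "\n")
    g <- group_by_axis(x, "cost_tier")
    cat("  cost tiers:",
        paste(sprintf("%s %d", g$group, g$n), collapse = ", "), "\n")
  }
  invisible(x)
}
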