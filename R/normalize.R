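# Label canonicalization and synonym clustering. Agreement must be counted
# over concepts, not strings: "FMF", "Familial Mediterranean Fever." and a
# candidate sharing code M04.1 are one diagnosis. Merging is deliberately
# conservative -- fuzzy string matching is off by default, because silent
# merges would hide exactly the minority diagnoses the framework exists to
# preserve.

#' Canonicalize a diagnosis label
#'
#' Lowercases, strips punctuation, collapses internal whitespace, and splits
#' off a trailing parenthetical as a secondary alias
#' (`"McArdle Disease (Glycogen Storage Disease V)"` canonicalizes to
#' `"mcardle disease"` with alias `"glycogen storage disease v"`).
#'
#' @param label Character vector of non-empty labels.
#' @param return_alias If `TRUE`, return a data frame with columns
#'   `canonical` and `alias` (`NA` when no trailing parenthetical); otherwise
#'   the canonical character vector.
#' @return Character vector, or data frame when `return_alias = TRUE`.
#' @export
#' @examples
#' canonicalize_label("Familial Mediterranean Fever.")
#' canonicalize_label("McArdle Disease (Glycogen Storage Disease V)",
#'                    return_alias = TRUE)
canonicalize_label <- function(label, return_alias = FALSE) {
  label <- as.character(label)
  if (length(label) == 0L || any(is.na(label)) || any(!nzchar(trimws(label)))) {
    stop_validation("cannot canonicalize an empty label")
  }
  alias <- rep(NA_character_, length(label))
  # strip trailing parenthetical before folding
  stripped <- sub("\\(([^()]*)\\)\\s*$", "", label)
  fold <- function(x) {
    x <- tolower(x)
    x <- gsub("['’]", "", x)          # apostrophes vanish: wilson's -> wilsons
    x <- gsub("[^a-z0-9]+", " ", x)        # other punctuation becomes a space
    trimws(gsub("\\s+", " ", x))
  }
  canonical <- fold(stripped)
  bad <- !nzchar(canonical)
  if (any(bad)) {
    # label was only punctuation/parenthetical; fall back to full fold
    canonical[bad] <- fold(label[bad])
    if (any(!nzchar(canonical))) {
      stop_validation("label canonicalizes to an empty string")
    }
  }
  m <- regexpr("\\(([^()]*)\\)\\s*$", label)
  hit <- m > 0
  if (any(hit)) {
    inner <- substring(label[hit], m[hit] + 1L,
                       m[hit] + attr(m, "match.length")[hit] - 2L)
    inner <- fold(inner)
    alias[hit][nzchar(inner)] <- inner[nzchar(inner)]
  }
  if (return_alias) {
    data.frame(canonical = canonical, alias = alias, stringsAsFactors = FALSE)
  } else {
    canonical
  }
}

#' Read a diagnosis alias table from YAML
#'
#' The file maps each canonical label to a list of aliases. Keys and values
#' are canonicalized on load, so the file can use natural spellings.
#'
#' @param path YAML file path.
#' @return A `dx_alias_table`: named list canonical -> character aliases.
#' @export
read_alias_table <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  tab <- lapply(doc, function(v) unique(canonicalize_label(as.character(v))))
  names(tab) <- canonicalize_label(names(doc))
  structure(tab, class = "dx_alias_table")
}

#' Shipped starter alias table
#'
#' Covers a set of named rare/regional diseases commonly returned under
#' several spellings (FMF, McArdle disease, Wilson's disease, Behcet's
#' disease, ...). Extend or replace via [read_alias_table()].
#'
#' @return A `dx_alias_table`.
#' @export
default_alias_table <- function() {
  cached <- .dx_cache$default_aliases
  if (is.null(cached)) {
    cached <- read_alias_table(system.file("extdata", "alias_table.yaml",
                                           package = "dxensemble",
                                           mustWork = TRUE))
    .dx_cache$default_aliases <- cached
  }
  cached
}

.dx_cache <- new.env(parent = emptyenv())

# alias -> canonical root map (canonical keys map to themselves)
alias_root_map <- function(aliases) {
  if (is.null(aliases) || length(aliases) == 0L) return(character(0))
  roots <- character(0)
  for (canon in names(aliases)) {
    roots[canon] <- canon
    for (al in aliases[[canon]]) roots[al] <- canon
  }
  roots
}

resolve_root <- function(canon, roots) {
  hit <- roots[canon]
  ifelse(is.na(hit), canon, hit)
}

# Minimal union-find over integer ids.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

new_cluster <- function(canonical_label, member_labels, icd10_codes,
                        supporting_model_ids, members, mean_confidence,
                        agreement_rate = NA_real_) {
  codes <- sort(unique(icd10_codes))
  cat3 <- unique(substr(codes, 1, 3))
  structure(
    list(canonical_label = canonical_label,
         member_labels = sort(unique(member_labels)),
         icd10_codes = codes,
         icd10_category = if (length(cat3) == 1L) cat3 else NA_character_,
         supporting_model_ids = sort(unique(supporting_model_ids)),
         members = members,
         mean_confidence = mean_confidence,
         agreement_rate = agreement_rate),
    class = "dx_cluster"
  )
}

#' Cluster synonymous diagnosis candidates across models
#'
#' Two candidates merge iff (a) their canonical labels are equal, (b) the
#' alias table links them, or (c) they share an identical full ICD-10 code.
#' Merging is transitive (connected components). A model supports a cluster
#' at most once regardless of how many of its candidates fall in it. The
#' cluster's `canonical_label` is the most frequent canonicalized member
#' label, ties broken lexicographically.
#'
#' Full-code equality is the default for rule (c): distinct diseases often
#' share a 3-character category, so category-level merging is opt-in via
#' `merge_icd10_category = TRUE`.
#'
#' @param responses List of `dx_response` objects, all for the same case.
#' @param aliases A `dx_alias_table` (default [default_alias_table()]).
#' @param merge_icd10_category If `TRUE`, also merge candidates sharing a
#'   3-character code category.
#' @return List of `dx_cluster` objects sorted by canonical label
#'   (`agreement_rate` unset; see [compute_agreement_rates()]).
#' @export
cluster_candidates <- function(responses, aliases = default_alias_table(),
                               merge_icd10_category = FALSE) {
  case_ids <- unique(vapply(responses, function(r) r$case_id, character(1)))
  if (length(case_ids) > 1L) {
    stop_validation(sprintf("responses mix case_ids: %s",
                            paste(case_ids, collapse = ", ")))
  }
  roots <- alias_root_map(aliases)

  model_l <- list(); label_l <- list(); conf_l <- list(); rank_l <- list()
  codes <- list()
  i <- 0L
  for (r in responses) {
    if (r$status != "ok") next
    for (cand in r$candidates) {
      i <- i + 1L
      model_l[[i]] <- r$model_id
      label_l[[i]] <- cand$label
      conf_l[[i]] <- cand$confidence
      rank_l[[i]] <- cand$rank
      codes[[i]] <- cand$icd10_codes
    }
  }
  n <- i
  if (n == 0L) return(list())
  model_id <- unlist(model_l); label <- unlist(label_l)
  conf <- unlist(conf_l); rank <- unlist(rank_l)
  ca <- canonicalize_label(label, return_alias = TRUE)
  canon <- ca$canonical
  canon_root <- resolve_root(canon, roots)
  alias_root <- ifelse(is.na(ca$alias), NA_character_,
                       resolve_root(ca$alias, roots))
  keys <- lapply(seq_len(n), function(j) {
    kk <- paste0("c:", canon_root[j])
    if (!is.na(alias_root[j])) kk <- c(kk, paste0("c:", alias_root[j]))
    if (length(codes[[j]]) > 0L) {
      kk <- c(kk, paste0("k:", codes[[j]]))
      if (merge_icd10_category) {
        kk <- c(kk, paste0("k3:", substr(codes[[j]], 1, 3)))
      }
    }
    kk
  })

  # union candidates sharing any key (linear in total keys, not pairwise)
  parent <- uf_new(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (k in keys[[i]]) {
      j <- seen[[k]]
      if (is.null(j)) {
        assign(k, i, envir = seen)
      } else {
        parent <- uf_union(parent, j, i)
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))

  clusters <- lapply(split(seq_len(n), comp), function(idx) {
    canons <- canon[idx]
    tab <- table(canons)
    top <- sort(names(tab)[tab == max(tab)])[1]
    new_cluster(
      canonical_label = top,
      member_labels = label[idx],
      icd10_codes = unlist(codes[idx]),
      supporting_model_ids = model_id[idx],
      members = data.frame(model_id = model_id[idx], label = label[idx],
                           rank = rank[idx], confidence = conf[idx],
                           stringsAsFactors = FALSE),
      mean_confidence = mean(conf[idx])
    )
  })
  names(clusters) <- NULL
  ord <- order(vapply(clusters, function(cl) cl$canonical_label, character(1)))
  clusters[ord]
}

#' @export
print.dx_cluster <- function(x, ...) {
  cat(sprintf("<dx_cluster> '%s' (%d supporter(s)%s, mean conf %.2f)\n",
              x$canonical_label, length(x$supporting_model_ids),
              if (!is.na(x$agreement_rate))
                sprintf(", agreement %.2f", x$agreement_rate) else "",
              x$mean_confidence))
  invisible(x)
}
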