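# Ensemble execution contract: query every registered client for every case,
# record exactly one status per (model, case) pair, tolerate failures, and
# keep results independent of execution order. Live API clients are out of
# the tested surface; the package ships the client contract, a mock client,
# and the synthetic ensemble so nothing here ever needs network access.

#' Construct a mock model client
#'
#' A client is a `model_id` plus a query handler. The handler receives a
#' `dx_case` and may return: a list of candidate lists (an "ok" response), a
#' `dx_response`, a status string (`"timeout"`, `"overflow"`, `"error"`), or
#' throw -- a thrown error is recorded as status `"error"`.
#'
#' @param model_id Client id (must exist in the registry at run time).
#' @param handler `function(case)` as described above.
#' @return A `dx_client`.
#' @export
mock_client <- function(model_id, handler) {
  if (!is_scalar_string(model_id)) stop_validation("model_id must be a string")
  if (!is.function(handler)) stop_validation("handler must be a function")
  structure(list(model_id = model_id, handler = handler),
            class = "dx_client")
}

client_query <- function(client, case, budget, lexicon) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(client$handler(case), error = function(e) "error")
  elapsed <- proc.time()[["elapsed"]] - t0
  resp <- if (inherits(out, "dx_response")) {
    out
  } else if (is.character(out) && length(out) == 1L &&
             out %in% c("timeout", "overflow", "error")) {
    new_response(client$model_id, case$case_id, status = out)
  } else if (is.list(out)) {
    parse_response(list(model_id = client$model_id, case_id = case$case_id,
                        status = "ok", candidates = out$candidates %||% out,
                        raw_text = out$raw_text), lexicon)
  } else {
    new_response(client$model_id, case$case_id, status = "error")
  }
  # contract: the orchestrator enforces the budget; clients are cooperative,
  # so over-budget completions are demoted to timeouts after the fact
  if (is.finite(budget) && elapsed > budget) {
    resp <- new_response(client$model_id, case$case_id, status = "timeout")
  }
  resp$model_id <- client$model_id
  resp$case_id <- case$case_id
  list(response = resp, elapsed = elapsed)
}

#' Run an ensemble of clients over a case set
#'
#' Queries every client for every case and records exactly one status per
#' (model, case) pair. Failures (timeout/overflow/error) produce
#' status-only responses. Results are sorted by (case_id, model_id), so
#' they are identical regardless of client order.
#'
#' @param clients List of `dx_client` objects.
#' @param cases List of `dx_case` objects.
#' @param registry A `dx_registry`; every client id must be present
#'   (checked before any query).
#' @param budget Per-query time budget in seconds (default `Inf`).
#' @param run_id Optional run identifier; derived from the client/case ids
#'   when omitted.
#' @param lexicon A `dx_lexicon` for scoring returned `raw_text`.
#' @return List with `responses` (sorted list of `dx_response`) and
#'   `run_record` (a `dx_run_record`: run id, ids, per-query status table,
#'   config snapshot, timing).
#' @export
run_ensemble <- function(clients, cases, registry, budget = Inf,
                         run_id = NULL, lexicon = default_lexicon()) {
  if (length(clients) == 0L) stop_validation("need at least one client")
  if (length(cases) == 0L) stop_validation("need at least one case")
  client_ids <- vapply(clients, function(cl) cl$model_id, character(1))
  if (anyDuplicated(client_ids)) {
    stop_validation("client model_ids must be unique")
  }
  missing <- setdiff(client_ids, registry$model_id)
  if (length(missing) > 0L) {
    stop_validation(sprintf("client id(s) missing from registry: %s",
                            paste(missing, collapse = ", ")))
  }
  case_ids <- vapply(cases, function(cc) cc$case_id, character(1))

  responses <- list()
  status_rows <- vector("list", length(clients) * length(cases))
  timing_rows <- vector("list", length(clients) * length(cases))
  k <- 0L
  for (case in cases) {
    for (client in clients) {
      res <- client_query(client, case, budget, lexicon)
      k <- k + 1L
      responses[[k]] <- res$response
      status_rows[[k]] <- data.frame(
        model_id = client$model_id, case_id = case$case_id,
        status = res$response$status, stringsAsFactors = FALSE)
      timing_rows[[k]] <- res$elapsed
    }
  }
  statuses <- do.call(rbind, status_rows)
  ord <- order(vapply(responses, function(r) r$case_id, character(1)),
               vapply(responses, function(r) r$model_id, character(1)))
  responses <- responses[ord]
  st_ord <- order(statuses$case_id, statuses$model_id)
  statuses <- statuses[st_ord, , drop = FALSE]
  rownames(statuses) <- NULL
  # wall-clock per query, informational only (kept out of statuses so the
  # run record is comparable across executions)
  timing <- data.frame(model_id = statuses$model_id,
                       case_id = statuses$case_id,
                       elapsed = unlist(timing_rows)[st_ord],
                       stringsAsFactors = FALSE)
  run_id <- run_id %||% sprintf("run-%08x", str_hash31(paste(
    c(sort(client_ids), sort(case_ids)), collapse = "|")))
  record <- structure(
    list(run_id = run_id, case_ids = sort(case_ids),
         model_ids = sort(client_ids), statuses = statuses,
         timing = timing, seed = NULL, config = list(budget = budget)),
    class = "dx_run_record"
  )
  list(responses = responses, run_record = record)
}

#' @export
print.dx_run_record <- function(x, ...) {
  cat(sprintf("<dx_run_record> %s: %d model(s) x %d case(s)\n",
              x$run_id, length(x$model_ids), length(x$case_ids)))
  print(table(x$statuses$status))
  invisible(x)
}
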