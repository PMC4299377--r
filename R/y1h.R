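#' Exclude auto-activating bait fragments
#'
#' Bait fragments that drive the reporter without any prey cannot be
#' screened; they are removed from the usable list (and therefore from hub
#' statistics). Exclusions are logged via `message()`.
#'
#' @param fragments data.frame with columns `fragment` and
#'   `auto_activating`.
#' @return the usable subset of `fragments`.
#' @export
filter_autoactivating <- function(fragments) {
  stopifnot(all(c("fragment", "auto_activating") %in% names(fragments)))
  drop <- fragments$fragment[fragments$auto_activating]
  if (length(drop))
    message("excluding auto-activating fragment(s): ",
            paste(drop, collapse = ", "))
  out <- fragments[!fragments$auto_activating, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call positive pools from growth observations
#'
#' A pool is positive when it grew on selective (AbA) medium *and* its
#' transformation control grew; a pool whose control failed is invalid
#' (to be repeated), never positive; anything else is negative. When a pool
#' id has repeated rows (a repeat round after a failed control), the last
#' valid observation wins.
#'
#' @param table Y1H observation data.frame (see [read_y1h_table()]).
#' @return data.frame of pool-stage rows with a `status` column
#'   (`positive` / `negative` / `invalid`).
#' @export
call_pools <- function(table) {
  pools <- table[table$stage == "pool", , drop = FALSE]
  if (!nrow(pools)) stop("data error: no pool-stage rows")
  pools$status <- ifelse(pools$control_growth == "no", "invalid",
                         ifelse(pools$growth == "yes", "positive", "negative"))
  # collapse repeat rounds: keep the last valid row per pool id, or the
  # last row if every attempt was invalid
  keep <- vapply(split(seq_len(nrow(pools)), pools$pool), function(idx) {
    valid <- idx[pools$status[idx] != "invalid"]
    if (length(valid)) valid[length(valid)] else idx[length(idx)]
  }, integer(1))
  out <- pools[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deconvolve positive pools into validated protein-DNA interactions
#'
#' Reproduces the screening logic: each member of a positive pool is
#' screened individually, and a PDI is reported only when the member's
#' individual transformation *and* its retest both grew. Positive pools in
#' which every individual was negative are logged as discordant (spurious
#' pool growth). Individual rows for TFs outside any positive pool are a
#' data error.
#'
#' @param table Y1H observation data.frame containing pool, individual and
#'   retest rows.
#' @return data.frame of validated PDIs: `tf`, `fragment`,
#'   `stage = "retest"`. The discordant pool ids are attached as
#'   `attr(, "discordant_pools")`.
#' @export
deconvolve <- function(table) {
  pools <- call_pools(table)
  positive <- pools[pools$status == "positive", , drop = FALSE]
  indiv <- table[table$stage == "individual", , drop = FALSE]
  retest <- table[table$stage == "retest", , drop = FALSE]

  pos_key <- positive$pool
  if (nrow(indiv) && any(!indiv$pool %in% pos_key))
    stop("data error: individual row for a TF not in any positive pool")

  pdis <- list()
  discordant <- character(0)
  for (i in seq_len(nrow(positive))) {
    pid <- positive$pool[i]
    frag <- positive$fragment[i]
    rows_i <- indiv[indiv$pool == pid, , drop = FALSE]
    any_indiv_pos <- FALSE
    for (j in seq_len(nrow(rows_i))) {
      tf <- rows_i$members[[j]]
      ok_i <- rows_i$growth[j] == "yes" && rows_i$control_growth[j] == "yes"
      if (!ok_i) next
      any_indiv_pos <- TRUE
      r <- retest[retest$pool == pid &
                    vapply(retest$members, identical, logical(1), tf), ,
                  drop = FALSE]
      ok_r <- nrow(r) > 0 && any(r$growth == "yes" & r$control_growth == "yes")
      if (ok_r)
        pdis[[length(pdis) + 1]] <- data.frame(tf = tf, fragment = frag)
    }
    if (!any_indiv_pos) discordant <- c(discordant, pid)
  }
  if (length(discordant))
    message("discordant positive pool(s) with no validated member: ",
            paste(discordant, collapse = ", "))
  out <- if (length(pdis)) do.call(rbind, pdis)
  else data.frame(tf = character(), fragment = character())
  out <- unique(out)
  out$stage <- rep("retest", nrow(out))
  rownames(out) <- NULL
  attr(out, "discordant_pools") <- discordant
  out
}
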