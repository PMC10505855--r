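#' Food-sharing-network degrees from reported sharing ties
#'
#' Computes each household's in-degree (number of distinct households
#' reported as giving food to it) and out-degree (distinct households it is
#' reported to give food to) from a directed edge list of sharing reports.
#' Following the study design, a household's own reports about itself are
#' excluded: a tie contributes to household h's degrees only if at least one
#' reporter outside h reported it. Self-loops are dropped, and duplicate
#' reports of the same tie count once.
#'
#' @param edges A data frame with columns `giver`, `receiver`, `reporter`
#'   (household ids). `reporter` is the household whose survey response the
#'   tie comes from.
#' @param households Character vector of household ids to report degrees for.
#' @return A tibble `household_id`, `in_degree`, `out_degree` in the order of
#'   `households`; all-zero for an empty edge list.
#' @export
#' @examples
#' edges <- tibble::tibble(
#'   giver = c("A", "A"), receiver = c("B", "C"), reporter = c("B", "C")
#' )
#' compute_network_degrees(edges, c("A", "B", "C"))
compute_network_degrees <- function(edges, households) {
  households <- unique(as.character(households))
  out <- tibble::tibble(
    household_id = households,
    in_degree = 0L,
    out_degree = 0L
  )
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    known <- unique(c(edges$giver, edges$receiver))
    unknown <- setdiff(known, households)
    if (length(unknown) > 0) {
      stop("edges reference unknown households: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    edges <- dplyr::filter(edges, .data$giver != .data$receiver)
    for (h in households) {
      # ties involving h, attested by some reporter other than h
      ties <- dplyr::filter(edges, .data$reporter != h)
      ties <- dplyr::distinct(ties, .data$giver, .data$receiver)
      out$in_degree[out$household_id == h] <-
        sum(ties$receiver == h)
      out$out_degree[out$household_id == h] <-
        sum(ties$giver == h)
    }
  }
  out
}
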