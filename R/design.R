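#' Generate one 12-trial block of virtual-hand location conditions
#'
#' Each block holds 4 trials per condition. Center trials sit at the fixed
#' positions 1, 6, 7 and 12 (beginning, middle and end of the block, with the
#' middle doubled so the count works out), which limits carry-over of the
#' drift induced by the lateral conditions. The two runs of four consecutive
#' lateral trials (one all-Left, one all-Right) fill positions 2-5 and 8-11
#' in randomized order.
#'
#' @param seed Optional integer seed for the lateral-order randomization.
#' @return Character vector of length 12 with values `"Left"`, `"Center"`,
#'   `"Right"`.
#' @examples
#' format_block(generate_block(seed = 1))
#' @export
generate_block <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lateral <- sample(c("Left", "Right"))
  c("Center", rep(lateral[1], 4), "Center",
    "Center", rep(lateral[2], 4), "Center")
}

#' One-letter rendering of a block
#'
#' @param block Character vector from [generate_block()].
#' @return A single string such as `"C L L L L C C R R R R C"`.
#' @export
format_block <- function(block) paste(substr(block, 1, 1), collapse = " ")

#' Generate the full experimental schedule
#'
#' Per participant: 10 blocks of 12 trials (4 per condition), i.e. 120 trials
#' (40 per condition). Group assignment alternates
#' synchronous/asynchronous, giving the 7/7 split at n = 14. Each block's
#' lateral ordering uses its own derived seed.
#'
#' @param n_participants Number of participants (0 gives an empty schedule).
#' @param seed Integer master seed.
#' @return A tibble with columns `pid`, `group`, `block` (1-10), `position`
#'   (1-12) and `condition`.
#' @examples
#' nrow(generate_schedule(14, seed = 1))
#' @export
generate_schedule <- function(n_participants, seed = 1) {
  empty <- tibble::tibble(pid = integer(), group = character(),
                          block = integer(), position = integer(),
                          condition = character())
  if (n_participants < 1) return(empty)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    purrr::map_dfr(1:10, function(blk) {
      tibble::tibble(
        pid = p,
        group = if (p %% 2 == 1) "synchronous" else "asynchronous",
        block = blk,
        position = 1:12,
        condition = generate_block(seed = derive_seed(seed, p, blk))
      )
    })
  })
}
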