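#' Construct a categorized stimulus set
#'
#' Builds the condition index shared by every RDM in an analysis: stimuli
#' organized as categories x exemplars (the experimental design uses 18
#' action categories, split into social and nonsocial actions, with 5
#' exemplar clips each, i.e. 90 conditions). Labels are deterministic so
#' that the ordering is fixed and shared by all downstream RDMs.
#'
#' @param n_categories number of categories (>= 1).
#' @param n_exemplars number of exemplars per category (>= 1).
#' @return a `stimulus_set`: a data frame with columns `stimulus_id`,
#'   `category`, `exemplar` and `social` (logical; the first half of the
#'   categories, rounded up, are flagged social).
#' @examples
#' s <- make_stimulus_set(18, 5)
#' nrow(s)  # 90
#' @export
make_stimulus_set <- function(n_categories, n_exemplars) {
  if (!is_count(n_categories) || !is_count(n_exemplars))
    stop_input("n_categories and n_exemplars must be positive counts")
  category <- rep(sprintf("cat%02d", seq_len(n_categories)),
                  each = n_exemplars)
  exemplar <- rep(seq_len(n_exemplars), times = n_categories)
  out <- data.frame(
    stimulus_id = sprintf("%s_e%d", category, exemplar),
    category = category,
    exemplar = exemplar,
    social = rep(seq_len(n_categories) <= ceiling(n_categories / 2),
                 each = n_exemplars),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_set", "data.frame")
  out
}
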