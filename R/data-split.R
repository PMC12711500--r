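#' Deterministic stratified holdout split
#'
#' `split_spec()` fixes the partition rule: per-class seeded shuffles with
#' round-half-up quotas. With the default 80:10:10 ratios and a class of
#' `n` items, the first `round(0.1 n)` shuffled items go to test, the next
#' `round(0.1 n)` to validation and the remainder to train, so every class
#' keeps the overall proportions within one item. The per-class random
#' generator is seeded from `(seed, class index)`, making membership fully
#' reproducible.
#'
#' @param ratios Numeric `(train, val, test)` ratios; positive, summing to 1
#'   within 1e-9.
#' @param seed Integer seed (default 1337).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(train = 0.8, val = 0.1, test = 0.1),
                       seed = 1337L) {
  if (length(ratios) != 3L || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop_caspnet("'ratios' must be three positive numbers")
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop_caspnet("'ratios' must sum to 1 (got ", format(sum(ratios)), ")")
  }
  structure(list(ratios = ratios, seed = check_count(seed, "seed", min = 0),
                 strategy = "stratified-holdout"),
            class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' @param set An `image_set` from [load_dataset()].
#' @param spec A [split_spec()].
#' @return A list with `image_set` elements `train`, `val`, `test`, plus a
#'   `manifest` data.frame (`path`, `class`, `split`).
#' @examples
#' \dontrun{
#' splits <- stratified_split(load_dataset("cells/"), split_spec())
#' sapply(splits[c("train", "val", "test")], length)
#' }
#' @export
stratified_split <- function(set, spec = split_spec()) {
  stopifnot(inherits(set, "image_set"), inherits(spec, "split_spec"))
  assign_split <- rep(NA_character_, nrow(set$items))
  for (ci in seq_along(set$class_names)) {
    idx <- which(set$items$class_idx == ci)
    n <- length(idx)
    if (n < 3L) {
      stop_caspnet(sprintf(
        "class '%s' has only %d item(s); at least 3 are required",
        set$class_names[ci], n))
    }
    perm <- with_seed(derive_seed(spec$seed, ci),
                      idx[sample.int(n)])
    n_test <- round_half_up(spec$ratios[3] * n)
    n_val <- round_half_up(spec$ratios[2] * n)
    assign_split[perm[seq_len(n_test)]] <- "test"
    assign_split[perm[n_test + seq_len(n_val)]] <- "val"
    train_pos <- setdiff(seq_len(n), seq_len(n_test + n_val))
    assign_split[perm[train_pos]] <- "train"
  }
  manifest <- data.frame(path = set$items$path,
                         class = set$items$class_name,
                         split = assign_split, stringsAsFactors = FALSE)
  list(train = subset_image_set(set, which(assign_split == "train")),
       val = subset_image_set(set, which(assign_split == "val")),
       test = subset_image_set(set, which(assign_split == "test")),
       manifest = manifest)
}
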