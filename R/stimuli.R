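#' Object shapes, color terms, and naming conditions
#'
#' The picture-naming design crosses five object shapes with five color
#' terms. Each image shows a colored object on a colored background, and the
#' naming task in each blocked condition determines which words are planned:
#' the object color alone (`"adjective"`), the object name alone (`"noun"`),
#' background color then object name (`"list"`), object color then object
#' name as a noun phrase (`"phrase"`), or the two colors
#' (`"color-control"`, not analysed).
#'
#' @format Character vectors of length 5.
#' @name design-constants
NULL

#' @rdname design-constants
#' @export
object_shapes <- c("bag", "bell", "cane", "lamp", "plane")

#' @rdname design-constants
#' @export
color_words <- c("black", "brown", "green", "red", "white")

#' @rdname design-constants
#' @export
naming_conditions <- c("adjective", "noun", "list", "phrase", "color-control")

#' Map a word category and naming context to the underlying condition
#'
#' Train/test regimes are named by *context*: `"isolation"` refers to the
#' single-word condition for the category at hand (the noun-only condition
#' for objects, the adjective-only condition for colors), while `"list"` and
#' `"phrase"` name those conditions directly.
#'
#' @param category `"object"` or `"color"`.
#' @param context `"isolation"`, `"list"`, or `"phrase"`.
#' @return The condition name.
#' @export
condition_for <- function(category, context) {
  category <- match.arg(category, c("object", "color"))
  context <- match.arg(context, c("isolation", "list", "phrase"))
  if (context == "isolation") {
    if (category == "object") "noun" else "adjective"
  } else {
    context
  }
}

#' Build the counterbalanced 50-image stimulus set
#'
#' Twenty-five base images pair each object shape with each object color;
#' background colors are assigned by a per-shape rotation of the color list
#' so that no image has matching object and background colors and each
#' background color appears equally often and equally across shapes. The 25
#' complementary images are obtained by swapping object and background
#' colors, giving 50 distinct images closed under that swap.
#'
#' @return A data frame with 50 rows and columns `object_shape`,
#'   `object_color`, `background_color`.
#' @examples
#' img <- build_stimulus_set()
#' nrow(img)                      # 50
#' all(img$object_color != img$background_color)
#' @export
build_stimulus_set <- function() {
  base <- expand.grid(
    object_shape = object_shapes,
    object_color = color_words,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # rotate background colors by a shape-dependent non-zero offset: the
  # rotation is a bijection per shape, so each color backs each shape once
  shape_idx <- match(base$object_shape, object_shapes)
  color_idx <- match(base$object_color, color_words)
  offset <- ((shape_idx - 1L) %% 4L) + 1L
  base$background_color <- color_words[((color_idx - 1L + offset) %% 5L) + 1L]
  swapped <- data.frame(
    object_shape = base$object_shape,
    object_color = base$background_color,
    background_color = base$object_color,
    stringsAsFactors = FALSE
  )
  out <- rbind(base, swapped)
  rownames(out) <- NULL
  out
}

# target words planned in a given condition for one image
target_words_for <- function(condition, image) {
  switch(condition,
    "adjective"     = c(image$object_color),
    "noun"          = c(image$object_shape),
    "list"          = c(image$background_color, image$object_shape),
    "phrase"        = c(image$object_color, image$object_shape),
    "color-control" = c(image$background_color, image$object_color),
    stop("unknown condition: ", condition, call. = FALSE)
  )
}

#' Build a blocked, counterbalanced trial schedule
#'
#' Each requested condition contributes 100 trials (the 50 stimulus images
#' presented twice), arranged in 4 blocks of 25 trials. Block order is
#' randomized under the constraint that two blocks of the same condition
#' never appear consecutively.
#'
#' @param conditions Character vector of conditions to include (default all
#'   five). A single condition cannot satisfy the non-adjacency constraint
#'   and raises an error.
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @return A data frame with one row per trial, in presentation order:
#'   `trial`, `condition`, `block` (global block id), `object_shape`,
#'   `object_color`, `background_color`, `word1`, `word2` (`NA` for
#'   single-word conditions), `word_color`, `word_object` (the planned word
#'   of each category, `NA` when that category is not planned or, for
#'   color-control, ambiguous).
#' @export
build_trial_schedule <- function(conditions = naming_conditions, seed) {
  conditions <- unique(as.character(conditions))
  if (length(conditions) == 0L || !all(conditions %in% naming_conditions)) {
    stop("`conditions` must be a non-empty subset of: ",
         paste(naming_conditions, collapse = ", "), call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_blocks_per_cond <- 4L
  # with equal block counts the constraint is unsatisfiable iff one condition
  # owns more than ceiling(total/2) blocks, i.e. iff only one condition
  if (length(conditions) == 1L && n_blocks_per_cond > 1L) {
    stop("cannot order ", n_blocks_per_cond, " blocks of a single condition ",
         "without two of them being adjacent", call. = FALSE)
  }
  images <- build_stimulus_set()
  with_seed(seed, {
    # non-adjacent block order by rejection sampling (fast for these counts)
    block_conds <- rep(conditions, each = n_blocks_per_cond)
    ord <- NULL
    for (try in seq_len(10000L)) {
      cand <- sample(block_conds)
      if (!any(cand[-1L] == cand[-length(cand)])) {
        ord <- cand
        break
      }
    }
    if (is.null(ord)) {
      stop("could not order blocks without adjacent repeats", call. = FALSE)
    }
    # per condition: 100 trials (50 images x 2), shuffled, cut into 4 blocks
    per_cond <- lapply(conditions, function(cond) {
      idx <- sample(rep(seq_len(nrow(images)), 2L))
      split(idx, rep(seq_len(n_blocks_per_cond), each = 25L))
    })
    names(per_cond) <- conditions
    next_block <- stats::setNames(rep(1L, length(conditions)), conditions)
    rows <- vector("list", length(ord))
    for (b in seq_along(ord)) {
      cond <- ord[b]
      idx <- per_cond[[cond]][[next_block[cond]]]
      next_block[cond] <- next_block[cond] + 1L
      img <- images[idx, , drop = FALSE]
      words <- t(vapply(seq_len(nrow(img)), function(i) {
        w <- target_words_for(cond, img[i, ])
        c(w, rep(NA_character_, 2L - length(w)))
      }, character(2L)))
      word_color <- switch(cond,
        "adjective" = img$object_color,
        "noun" = rep(NA_character_, nrow(img)),
        "list" = img$background_color,
        "phrase" = img$object_color,
        "color-control" = rep(NA_character_, nrow(img))  # two colors: ambiguous
      )
      word_object <- switch(cond,
        "adjective" = rep(NA_character_, nrow(img)),
        "noun" = img$object_shape,
        "list" = img$object_shape,
        "phrase" = img$object_shape,
        "color-control" = rep(NA_character_, nrow(img))
      )
      rows[[b]] <- data.frame(
        condition = cond, block = b,
        object_shape = img$object_shape,
        object_color = img$object_color,
        background_color = img$background_color,
        word1 = words[, 1L], word2 = words[, 2L],
        word_color = word_color, word_object = word_object,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    out <- cbind(trial = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}
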