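#' Load a food table
#'
#' Reads a CSV with columns `name`, `weight` (g) and `calorie` (kcal).
#' Calorie cells reading `"N/a"` denote a missing nutrition-table value and
#' are parsed as `NA`, which is distinct from an explicit `0.00` (a printed
#' zero means "below the labelling minimum" and is only replaced later, in
#' the regression loss; see [replace_zero_calories()]).
#'
#' @param source path to a CSV file. Defaults to the packaged fixture of
#'   the 101-item study table.
#' @return data.frame with columns `item_id`, `name`, `weight_g`,
#'   `calorie_kcal` (NA when missing) and `class_index` (0-based).
#' @examples
#' ft <- load_food_table()
#' nrow(ft)            # 101
#' sum(is.na(ft$calorie_kcal))  # 3
#' @export
load_food_table <- function(source = food_table_fixture()) {
  if (!file.exists(source)) stop("food table not found: ", source)
  d <- utils::read.csv(source, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("name", "weight", "calorie")
  if (!all(need %in% names(d))) {
    stop("food table must have columns name, weight, calorie; got: ",
         paste(names(d), collapse = ", "))
  }
  if (nrow(d) == 0) stop("food table is empty: ", source)
  weight <- suppressWarnings(as.numeric(d$weight))
  cal_raw <- trimws(d$calorie)
  missing_cal <- tolower(cal_raw) %in% c("n/a", "na", "")
  calorie <- suppressWarnings(as.numeric(cal_raw))
  bad <- which(is.na(weight) | weight <= 0 |
                 (!missing_cal & (is.na(calorie) | calorie < 0)))
  if (length(bad)) {
    stop("malformed food table row(s) ", paste(bad, collapse = ", "),
         " (item: ", paste(d$name[bad], collapse = ", "), ")")
  }
  calorie[missing_cal] <- NA_real_
  data.frame(
    item_id = seq_len(nrow(d)),
    name = d$name,
    weight_g = weight,
    calorie_kcal = calorie,
    class_index = seq_len(nrow(d)) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Path to the packaged 101-item food table fixture
#' @return file path of the CSV shipped with the package.
#' @export
food_table_fixture <- function() {
  system.file("extdata", "food_table.csv", package = "calospec",
              mustWork = TRUE)
}

#' Summary statistics of a food table
#'
#' Mean and standard deviation of weight over all items and of calories
#' over items with a present calorie value, matching the footer layout of
#' the study's dataset table. Sample (n-1) normalization is used.
#'
#' @param items data.frame as returned by [load_food_table()].
#' @return list with `mean_weight_g`, `std_weight_g`, `mean_calorie_kcal`,
#'   `std_calorie_kcal`, `n_items`, `n_missing_calorie`.
#' @examples
#' s <- summarize_food_table(load_food_table())
#' round(c(s$std_weight_g, s$std_calorie_kcal), 2)
#' @export
summarize_food_table <- function(items) {
  stopifnot(is.data.frame(items),
            all(c("weight_g", "calorie_kcal") %in% names(items)))
  w <- items$weight_g
  cal <- items$calorie_kcal[!is.na(items$calorie_kcal)]
  if (length(w) < 2 || length(cal) < 2) {
    stop("need at least 2 usable values per column to compute a standard deviation")
  }
  list(
    mean_weight_g = mean(w),
    std_weight_g = stats::sd(w),
    mean_calorie_kcal = mean(cal),
    std_calorie_kcal = stats::sd(cal),
    n_items = nrow(items),
    n_missing_calorie = sum(is.na(items$calorie_kcal))
  )
}
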