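# Reference catalog: the 34 Indonesian hospital-meal categories of the
# 524-pair plate-waste survey that this package's defaults emulate, with the
# number of annotated pairs per category and per observer level (1 = not
# consumed at all ... 7 = zero remaining).
.reference_rows <- function() {
  txt <- "
food_id|food_name|total|l1|l2|l3|l4|l5|l6|l7
1|Bubur (Porridge)|1|1|0|0|0|0|0|0
2|Nasi (Rice)|78|14|1|7|8|11|9|28
3|Tim (Rice Porridge)|76|9|1|8|14|9|8|27
4|Telur Orak Arik (Scrambled Eggs)|1|1|0|0|0|0|0|0
5|Kroket Daging (Meat Croquettes)|19|2|0|0|0|2|1|14
6|Opor Ayam (Chicken Braised in Coconut Milk)|2|1|0|0|0|0|0|1
7|Opor Telur (Opor Eggs)|2|1|0|0|0|0|1|0
8|Ikan Acar Kuning (Yellow Pickled Fish)|20|6|1|1|2|2|1|7
9|Bali Putih Telur (Bali Egg White)|4|0|0|0|1|0|2|1
10|Bali Telur (Bali Eggs)|21|5|0|0|2|0|1|13
11|Ayam Bumbu Srundeng (Srundeng Seasoned Chicken)|9|3|0|0|1|1|1|3
12|Rendang Ayam (Chicken Rendang)|18|3|1|2|0|1|4|7
13|Ayam Bumbu Laos (Galangal Seasoned Chicken)|16|7|1|1|1|1|2|3
14|Ayam Bumbu Bistik (Steak Seasoned Chicken)|22|3|0|0|3|2|5|9
15|Ikan Bb Asam Manis (Sweet and Sour Seasoned Fish)|14|0|1|2|2|0|2|7
16|Telur Mata Sapi (Sunny Side Up)|20|3|0|0|1|2|2|12
17|Ayam Suwir (Shredded Chicken)|5|0|0|1|0|1|0|3
18|Oseng Bakso (Stir Fry Meatballs)|5|0|0|0|2|0|1|2
19|Oseng Sosis (Stir Fry Sausage)|4|1|1|0|0|0|0|2
20|Sambel Goreng Rempela Ati (Sambal Goreng Rempela Ati)|15|9|0|0|0|0|2|4
21|Bola Bola Daging (Meat Balls)|6|0|0|0|1|0|0|5
22|Tumis Bakso (Stir Fry Meatballs)|12|1|2|0|0|0|1|8
23|Dadar Jagung Goreng (Fried Corn Omelet)|6|0|0|0|1|0|0|5
24|Bali Tahu (Balinese Tofu)|22|10|2|0|0|0|0|10
25|Perkedel Kentang (Potato Cakes)|22|3|0|0|2|1|0|16
26|Tahu Goreng (Fried Tofu)|1|0|0|0|0|0|0|1
27|Tahu Bumbu Kecap (Tofu Soy Sauce)|19|4|3|2|3|0|1|6
28|Tempe Bumbu Kuning (Yellow Seasoning Tempeh)|3|0|0|0|1|0|1|1
29|Tempe Goreng (Fried Tempe)|6|3|0|0|0|0|0|3
30|Tempe Bumbu Bacem (Seasoned Tempeh)|28|6|1|1|1|1|2|16
31|Tahu Bulat (Round Tofu)|11|5|0|0|0|1|1|4
32|Orek Tempe (Orek Tempeh)|22|3|0|0|5|2|2|10
33|Dadar Jagung Kukus (Steamed Corn Omelet)|3|2|0|0|0|1|0|0
34|Oseng Tahu (Oseng Tofu)|11|1|2|2|3|1|1|1
"
  read.csv(text = trimws(txt), sep = "|", stringsAsFactors = FALSE)
}

#' Food category catalog
#'
#' A catalog maps integer food ids to food names. The default catalog holds
#' the 34 categories of the hospital plate-waste survey the package's
#' defaults emulate; custom catalogs must use ids that are unique and
#' contiguous from 1.
#'
#' @param entries `NULL` for the default 34-category catalog, an integer
#'   `n <= 34` for its first `n` categories, or a data frame with columns
#'   `food_id` and `food_name`.
#' @return A `food_catalog`: a data frame with columns `food_id`, `food_name`.
#' @examples
#' cat34 <- food_catalog()
#' nrow(cat34)
#' food_catalog(8)
#' @export
food_catalog <- function(entries = NULL) {
  ref <- .reference_rows()[, c("food_id", "food_name")]
  if (is.null(entries)) {
    df <- ref
  } else if (is.numeric(entries) && length(entries) == 1L) {
    n <- as.integer(entries)
    if (n < 1L || n > nrow(ref)) {
      stop("a numeric catalog size must be between 1 and ", nrow(ref),
           call. = FALSE)
    }
    df <- ref[seq_len(n), ]
  } else if (is.data.frame(entries)) {
    if (!all(c("food_id", "food_name") %in% names(entries))) {
      stop("catalog entries need columns 'food_id' and 'food_name'",
           call. = FALSE)
    }
    df <- data.frame(food_id = as.integer(entries$food_id),
                     food_name = as.character(entries$food_name),
                     stringsAsFactors = FALSE)
  } else {
    stop("unsupported 'entries'", call. = FALSE)
  }
  df <- df[order(df$food_id), , drop = FALSE]
  if (anyDuplicated(df$food_id) || !identical(df$food_id, seq_len(nrow(df)))) {
    stop("food ids must be unique and contiguous from 1", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("food_catalog", "data.frame")
  df
}

#' Reference per-level pair counts
#'
#' The number of annotated image pairs per category and per observer level
#' (1--7) in the 524-pair reference survey. Useful for building fixtures that
#' mirror the survey's category and level imbalance.
#'
#' @return Data frame with columns `food_id`, `food_name`, `total`,
#'   `l1` ... `l7`; the `total` column sums to 524 over the 34 rows.
#' @export
reference_pair_counts <- function() {
  df <- .reference_rows()
  stopifnot(all(rowSums(df[paste0("l", 1:7)]) == df$total))
  df
}
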