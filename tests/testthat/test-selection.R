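# Deterministic mock loss: distance of the candidate set from a target set.
sym_diff_loss <- function(target) {
  function(s) length(union(setdiff(s, target), setdiff(target, s)))
}

test_that("forward, backward and final-forward match exhaustive enumeration on the worked example", {
  loss <- sym_diff_loss(c("a", "c"))
  fw <- forward_step(character(0), c("a", "b", "c"), loss)
  expect_equal(fw$added, "a")  # a/c tie broken to the first label
  expect_equal(fw$loss, 1)

  bw <- backward_step(c("a", "c"), loss)
  expect_equal(bw$removed, "a")  # removal tie broken to the first label
  expect_equal(sort(bw$set), "c")

  ff <- final_forward_step("c", c("a", "b", "c"), loss)
  expect_equal(ff$added, "a")
  expect_setequal(ff$set, c("a", "c"))
  expect_equal(ff$loss, 0)

  # singleton backward empties the set; single candidate is forced
  expect_equal(backward_step("a", loss)$set, character(0))
  expect_equal(forward_step(c("a", "c"), c("a", "b", "c"), loss)$added, "b")
  expect_error(forward_step(c("a", "b", "c"), c("a", "b", "c"), loss),
               "complement")
})

test_that("the full worked selection run ends at the target set", {
  res <- run_selection(c("a", "b", "c"), sym_diff_loss(c("a", "c")))
  expect_setequal(res$optimum, c("a", "c"))
  expect_equal(res$optimum_loss, 0)
  expect_equal(res$per_cardinality$size, 1:3)
  # exhaustive search over all 7 non-empty subsets agrees
  subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(c("a", "b", "c"), k, simplify = FALSE)
  }), recursive = FALSE)
  best <- subsets[[which.min(vapply(subsets, sym_diff_loss(c("a", "c")), 1.0))]]
  expect_setequal(res$optimum, best)
})

test_that("every step argmin matches exhaustive enumeration for random mock losses", {
  set.seed(19)
  labels4 <- c("a", "b", "c", "d")
  for (rep in 1:25) {
    n <- sample(3:4, 1)
    labels <- labels4[seq_len(n)]
    # a random deterministic loss over all subsets, keyed by canonical name
    tbl <- new.env()
    loss <- function(s) {
      key <- subset_key(s)
      if (is.null(tbl[[key]])) tbl[[key]] <- stats::runif(1)
      tbl[[key]]
    }
    # pre-populate so the loss is a fixed function
    for (k in 0:n) {
      for (s in utils::combn(labels, k, simplify = FALSE)) loss(s)
    }
    current <- sample(labels, sample(0:(n - 1), 1))
    fw <- forward_step(current, labels, loss)
    cand <- setdiff(labels, current)
    expect_equal(fw$added, brute_step_argmin(
      cand, lapply(cand, function(w) union(current, w)), loss))
    if (length(fw$set) >= 2) {
      bw <- backward_step(fw$set, loss)
      expect_equal(bw$removed, brute_step_argmin(
        fw$set, lapply(fw$set, function(w) setdiff(fw$set, w)), loss))
      if (length(bw$set) < n) {
        ff <- final_forward_step(bw$set, labels, loss)
        cand2 <- setdiff(labels, bw$set)
        expect_equal(ff$added, brute_step_argmin(
          cand2, lapply(cand2, function(w) union(bw$set, w)), loss))
      }
    }
  }
})

test_that("each iteration grows the working set by exactly one wavelength", {
  set.seed(23)
  labels <- c("385", "470", "890", "970", "RGB")
  loss <- function(s) stats::runif(1)  # memoized, so still deterministic per set
  res <- run_selection(labels, loss, include_rgb = TRUE)
  expect_equal(res$per_cardinality$size, 1:5)
  res2 <- run_selection(labels[1:4], loss)
  expect_equal(res2$per_cardinality$size, 1:4)
})

test_that("RGB mode keeps RGB permanent and never eliminates it", {
  loss <- sym_diff_loss(c("RGB", "890"))
  expect_error(run_selection(c("385", "890"), loss, include_rgb = TRUE),
               "requires RGB")
  res <- run_selection(c("RGB", "385", "890", "970"), loss,
                       include_rgb = TRUE)
  for (s in res$per_cardinality$set) {
    expect_true(grepl("RGB", s))
  }
  expect_setequal(res$optimum, c("RGB", "890"))
  bw <- backward_step(c("RGB", "890"), loss, include_rgb = TRUE)
  expect_equal(bw$removed, "890")
  expect_error(backward_step("RGB", loss, include_rgb = TRUE), "removable")
})

test_that("additive losses select the single cheapest wavelength", {
  w <- c(a = 3, b = 1, c = 2)
  loss <- function(s) if (!length(s)) 10 else sum(w[s])
  res <- run_selection(c("a", "b", "c"), loss)
  expect_equal(res$optimum, "b")
  expect_equal(res$optimum_loss, 1)
})

test_that("memoization evaluates each set once and records every call", {
  calls <- 0
  loss <- memoize_loss(function(s) { calls <<- calls + 1; length(s) })
  loss(c("a", "b")); loss(c("b", "a")); loss("a")
  expect_equal(calls, 2)
  log <- loss_evaluations(loss)
  expect_equal(nrow(log), 3)
  expect_equal(log$cached, c(FALSE, TRUE, FALSE))
})

test_that("selection rate summaries count frequencies and band shares", {
  loss <- sym_diff_loss(c("RGB", "890"))
  res <- run_selection(c("RGB", "385", "470", "890"), loss,
                       include_rgb = TRUE)
  rates <- selection_rate_summary(res)
  freq <- rates$frequency
  expect_equal(freq$rate[freq$wavelength == "890"], 3 / 4, tolerance = 1e-9)
  expect_equal(sum(freq$count), rates$n_slots)
  expect_equal(sum(rates$band_share), 100, tolerance = 1e-9)
  capped <- selection_rate_summary(res, max_images = 2)
  expect_lt(capped$n_sets, rates$n_sets)
})

test_that("selection results expose an audit trace with recorded losses", {
  loss <- sym_diff_loss(c("a", "c"))
  res <- run_selection(c("a", "b", "c"), loss)
  expect_true(all(c("set", "size", "loss", "cached") %in% names(res$trace)))
  expect_equal(min(res$trace$loss), res$optimum_loss)
})
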