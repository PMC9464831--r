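# The decoding lattice: completeness of the node inventory, the
# size/channel contracts, and bit-exact agreement between chained and
# stepwise upsampling.

lattice_fixture <- function(input = 64L, widths = c(8, 16, 24, 32, 48, 64),
                            chain = NULL, seed = 1) {
  set.seed(seed)
  img <- array(runif(input * input * 3), c(input, input, 3))
  maps <- encode(img, encoder_spec(widths = widths), seed = seed)
  set.seed(seed + 1)
  dec <- if (is.null(chain)) lfa_decoder(widths) else lfa_decoder(widths, chain)
  list(maps = maps, dec = dec, out = lfa_forward(maps, dec), input = input)
}

test_that("the lattice contains exactly the nodes the aggregation scheme defines", {
  fx <- lattice_fixture()
  inv <- lattice_inventory(fx$out$lattice)
  # encoder column, chain nodes (i <= 7 - j), five aggregated maps, one
  # upsampled level-1 chain node
  want_n <- 6 + (5 + 4 + 3 + 2) + 1 + 5
  expect_equal(nrow(inv), want_n)
  expect_equal(sum(inv$role == "encoder"), 6)
  expect_equal(sum(inv$role == "aggregated"), 5)
  expect_equal(sum(inv$role == "chain"), 14)
  expect_equal(sum(inv$role == "upsampled"), 1)
  for (r in seq_len(nrow(inv))) {
    expect_equal(inv$height[r], fx$input / 2^(inv$i[r] - 1),
                 label = sprintf("height of node (%d,%d)", inv$i[r], inv$j[r]))
  }
  agg <- inv[inv$role == "aggregated", ]
  expect_setequal(paste(agg$i, agg$j), c("1 6", "2 6", "3 5", "4 4", "5 3"))
})

test_that("aggregated channel counts equal the concatenation sums", {
  widths <- c(8, 16, 24, 32, 48, 64)
  fx <- lattice_fixture(widths = widths, chain = 8)
  # with constant chain width d: agg_i = C_i + (6 - i) * d
  expect_equal(fx$dec$agg_widths, widths[1:5] + (6 - 1:5) * 8)
  expect_equal(dim(fx$out$lattice[["5,3"]])[3], 48 + 8)
  got <- vapply(list("1,6", "2,6", "3,5", "4,4", "5,3"),
                function(k) dim(fx$out$lattice[[k]])[3], numeric(1))
  expect_equal(unname(got), fx$dec$agg_widths)
  # default chain widths are ceiling(C_i / 2)
  expect_equal(lfa_decoder(widths)$chain_widths, ceiling(widths[1:5] / 2))
})

test_that("running the chain stepwise reproduces the lattice nodes bit-exactly", {
  fx <- lattice_fixture()
  x <- fx$maps[[6]]
  for (i in 5:1) {
    x <- upsample_step(x, fx$dec$chains[[1]][[i]])
    expect_identical(drop(x), drop(fx$out$lattice[[paste0(i, ",2")]]),
                     label = sprintf("chain-1 node at level %d", i))
  }
})

test_that("aggregated outputs have the level sizes and order the scheme demands", {
  fx <- lattice_fixture(input = 64L)
  sizes <- vapply(fx$out$aggregated, function(m) dim(m)[1], numeric(1))
  expect_equal(sizes, 64 / 2^(0:4))
})

test_that("aggregate_level concatenates in order and validates shapes", {
  a <- array(1, c(4, 4, 2)); b <- array(2, c(4, 4, 3))
  out <- aggregate_level(list(a, b))
  expect_equal(dim(out)[3], 5L)
  expect_true(all(out[, , 1:2, 1] == 1) && all(out[, , 3:5, 1] == 2))
  expect_equal(aggregate_level(list(a)), as_feature_map(a))
  bad <- array(0, c(8, 8, 1))
  expect_error(aggregate_level(list(a, bad)), "mismatch")
})
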