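#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Pairwise affinity of 6-adjacent voxels from the two 1-D tables.
// sum_table[s] = g1(s/2), diff_table[u] = g2(u/2); taking sqrt of each factor
// separately keeps the result strictly positive even when both factors sit at
// the denormal floor.
static inline double mu_tab(const double* st, const double* dt, int fa, int fb) {
    return std::sqrt(st[fa + fb]) * std::sqrt(dt[std::abs(fa - fb)]);
}

static const int DX[6] = { -1, 1, 0, 0, 0, 0 };
static const int DY[6] = { 0, 0, -1, 1, 0, 0 };
static const int DZ[6] = { 0, 0, 0, 0, -1, 1 };

// Sequential reference: best-first (descending connectivity) extraction over
// the max-min semiring, lazy re-insertion, FIFO tie-break via an insertion
// counter so traces are reproducible.
// [[Rcpp::export]]
NumericVector cpp_reference(IntegerVector f, IntegerVector dim,
                            IntegerVector seed_idx,
                            NumericVector sum_table, NumericVector diff_table) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector val(n, 0.0);
    const double* st = REAL(sum_table);
    const double* dt = REAL(diff_table);
    const int* ff = INTEGER(f);

    // (value, (-insertion counter, index)): max value first, FIFO among ties
    typedef std::pair<double, std::pair<long long, int> > QE;
    std::priority_queue<QE> pq;
    long long counter = 0;
    for (int k = 0; k < seed_idx.size(); ++k) {
        int s = seed_idx[k];
        val[s] = 1.0;
        pq.push(QE(1.0, std::make_pair(-(counter++), s)));
    }
    while (!pq.empty()) {
        double v = pq.top().first;
        int c = pq.top().second.second;
        pq.pop();
        if (v < val[c]) continue;  // stale entry
        int x = c % nx, r = c / nx;
        int y = r % ny, z = r / ny;
        for (int k = 0; k < 6; ++k) {
            int X = x + DX[k], Y = y + DY[k], Z = z + DZ[k];
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            int d = X + nx * (Y + ny * Z);
            double cand = std::min(v, mu_tab(st, dt, ff[c], ff[d]));
            if (cand > val[d]) {
                val[d] = cand;
                pq.push(QE(cand, std::make_pair(-(counter++), d)));
            }
        }
    }
    return val;
}

// xorshift32; self-contained so block schedules are bit-reproducible across
// platforms (std::shuffle is implementation-defined).
struct XorShift32 {
    uint32_t s;
    explicit XorShift32(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {}
    uint32_t next() {
        s ^= s << 13; s ^= s >> 17; s ^= s << 5;
        return s;
    }
    // uniform in [0, m) by rejection
    uint32_t below(uint32_t m) {
        uint32_t lim = UINT32_MAX - (UINT32_MAX % m);
        uint32_t v;
        do { v = next(); } while (v >= lim);
        return v % m;
    }
};

// Block-parallel propagation emulator.
//
// policy: 0 = synchronous      (value reads from a pass-start snapshot,
//                               activation marks double-buffered into the
//                               next pass's flag array)
//         1 = seq. asynchronous(live value reads; live flag reads, so a block
//                               scheduled later in the pass processes marks
//                               set earlier in the same pass; no mark loss)
//         2 = adversarial      (as 1, plus the flag race of the original
//                               block-parallel scheme: a cross-block
//                               re-activation of a voxel already processed in
//                               the current pass is lost -- the value is still
//                               max-updated but the voxel is not re-queued)
//
// n_passes  = -1: iterate to quiescence, then run correction rounds;
// n_passes >=  0: run exactly that many passes and return the state
//                 (correction is skipped in that mode).
// [[Rcpp::export]]
List cpp_block_solve(IntegerVector f, IntegerVector dim,
                     NumericVector fc_init, LogicalVector active_init,
                     NumericVector sum_table, NumericVector diff_table,
                     IntegerMatrix block_lo, IntegerMatrix block_hi,
                     int policy, IntegerVector explicit_order, int rng_seed,
                     int n_passes, int correction_directions,
                     int max_correction_rounds) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const int nb = block_lo.nrow();
    const double* st = REAL(sum_table);
    const double* dt = REAL(diff_table);
    const int* ff = INTEGER(f);

    std::vector<double> fc(fc_init.begin(), fc_init.end());
    std::vector<char> act(n, 0);
    for (R_xlen_t i = 0; i < n; ++i) act[i] = active_init[i] ? 1 : 0;

    // voxel -> block id
    std::vector<int> block_of(n, -1);
    for (int b = 0; b < nb; ++b) {
        for (int z = block_lo(b, 2); z <= block_hi(b, 2); ++z)
            for (int y = block_lo(b, 1); y <= block_hi(b, 1); ++y)
                for (int x = block_lo(b, 0); x <= block_hi(b, 0); ++x)
                    block_of[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = b;
    }

    XorShift32 rng((uint32_t)rng_seed * 2654435761u + 1u);
    std::vector<int> order(nb);
    for (int b = 0; b < nb; ++b) order[b] = b;
    const bool fixed_order = explicit_order.size() > 0;
    if (fixed_order) {
        for (int b = 0; b < nb; ++b) order[b] = explicit_order[b];
    }

    std::vector<int> stamp(n, 0);        // pass in which a voxel was processed
    std::vector<char> nxt;               // synchronous next-pass flags
    std::vector<double> snap;            // synchronous value snapshot
    int pass_no = 0;
    long long pass_guard = 20LL * n + 1000LL;

    // one full pass over all blocks; returns true if any voxel was processed
    // or any flag survives into the next pass
    auto run_pass = [&]() -> bool {
        ++pass_no;
        if (!fixed_order && policy != 0) {
            // fresh shuffle each pass (Fisher-Yates)
            for (int b = 0; b < nb; ++b) order[b] = b;
            for (int b = nb - 1; b > 0; --b) {
                int j = (int)rng.below((uint32_t)(b + 1));
                std::swap(order[b], order[j]);
            }
        }
        if (policy == 0) {
            snap.assign(fc.begin(), fc.end());
            nxt.assign(n, 0);
        }
        for (int ob = 0; ob < nb; ++ob) {
            int b = order[ob];
            for (int z = block_lo(b, 2); z <= block_hi(b, 2); ++z)
                for (int y = block_lo(b, 1); y <= block_hi(b, 1); ++y)
                    for (int x = block_lo(b, 0); x <= block_hi(b, 0); ++x) {
                        R_xlen_t c = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                        if (!act[c]) continue;
                        act[c] = 0;
                        stamp[c] = pass_no;
                        double fv = (policy == 0) ? snap[c] : fc[c];
                        for (int k = 0; k < 6; ++k) {
                            int X = x + DX[k], Y = y + DY[k], Z = z + DZ[k];
                            if (X < 0 || X >= nx || Y < 0 || Y >= ny ||
                                Z < 0 || Z >= nz) continue;
                            R_xlen_t d = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
                            double cand = std::min(fv, mu_tab(st, dt, ff[c], ff[d]));
                            if (cand > fc[d]) {  // emulated atomic max
                                fc[d] = cand;
                                if (policy == 0) {
                                    nxt[d] = 1;
                                } else {
                                    bool lost = (policy == 2 &&
                                                 block_of[d] != b &&
                                                 stamp[d] == pass_no);
                                    if (!lost) act[d] = 1;
                                }
                            }
                        }
                    }
        }
        if (policy == 0) act.swap(nxt);  // double-buffer swap
        for (R_xlen_t i = 0; i < n; ++i) if (act[i]) return true;
        return false;
    };

    auto run_to_quiescence = [&]() {
        bool any = false;
        for (R_xlen_t i = 0; i < n; ++i) if (act[i]) { any = true; break; }
        while (any) {
            any = run_pass();
            if (pass_no > pass_guard)
                stop("propagation failed to terminate (internal error)");
        }
    };

    int rounds = 0;
    if (n_passes >= 0) {
        for (int p = 0; p < n_passes; ++p) run_pass();
    } else {
        run_to_quiescence();
        if (correction_directions > 0) {
            std::vector<double> before(n);
            for (int r = 0; r < max_correction_rounds; ++r) {
                before.assign(fc.begin(), fc.end());
                // re-activate block-face voxels for the first
                // `correction_directions` entries of (-x,+x,-y,+y,-z,+z)
                for (int b = 0; b < nb; ++b) {
                    int lo0 = block_lo(b, 0), hi0 = block_hi(b, 0);
                    int lo1 = block_lo(b, 1), hi1 = block_hi(b, 1);
                    int lo2 = block_lo(b, 2), hi2 = block_hi(b, 2);
                    for (int z = lo2; z <= hi2; ++z)
                        for (int y = lo1; y <= hi1; ++y)
                            for (int x = lo0; x <= hi0; ++x) {
                                bool on_face =
                                    (correction_directions > 0 && x == lo0) ||
                                    (correction_directions > 1 && x == hi0) ||
                                    (correction_directions > 2 && y == lo1) ||
                                    (correction_directions > 3 && y == hi1) ||
                                    (correction_directions > 4 && z == lo2) ||
                                    (correction_directions > 5 && z == hi2);
                                if (on_face)
                                    act[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = 1;
                            }
                }
                run_to_quiescence();
                ++rounds;
                if (std::memcmp(before.data(), fc.data(),
                                n * sizeof(double)) == 0) break;
            }
        }
    }

    NumericVector fc_out(fc.begin(), fc.end());
    LogicalVector act_out(n);
    for (R_xlen_t i = 0; i < n; ++i) act_out[i] = act[i] != 0;
    return List::create(_["fc"] = fc_out, _["active"] = act_out,
                        _["passes"] = pass_no, _["rounds"] = rounds);
}
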