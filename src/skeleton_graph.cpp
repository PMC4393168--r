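#include <Rcpp.h>
#include <vector>
#include <set>
#include <queue>
using namespace Rcpp;

// Segment extraction from a thinned (one-voxel-wide) skeleton under
// 26-connectivity. Node voxels (degree >= 3) are merged into clusters so a
// thick junction counts as a single node; segments run node-to-node,
// node-to-free-end, end-to-end (isolated vessels) or form pure cycles.
// Terminus codes: 0 = node cluster, 1 = free end, 2 = cycle closure,
// 3 = isolated voxel.

static const int NB = 26;
static int OFF[26][3];
static void init_off() {
  int n = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        OFF[n][0] = dx; OFF[n][1] = dy; OFF[n][2] = dz; ++n;
      }
}

// [[Rcpp::export]]
List skeleton_segments_cpp(LogicalVector skel, IntegerVector dims) {
  init_off();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  R_xlen_t plane = (R_xlen_t)n1 * n2;

  std::vector<int> deg(N, -1);
  std::vector<R_xlen_t> vox;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)j * n1 + (R_xlen_t)k * plane;
        if (!skel[idx]) continue;
        int cnt = 0;
        for (int t = 0; t < NB; ++t) {
          int ii = i + OFF[t][0], jj = j + OFF[t][1], kk = k + OFF[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
          if (skel[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * plane]) ++cnt;
        }
        deg[idx] = cnt;
        vox.push_back(idx);
      }

  // cluster node voxels (degree >= 3)
  std::vector<int> cluster(N, 0);
  int ncl = 0;
  for (size_t s = 0; s < vox.size(); ++s) {
    R_xlen_t idx = vox[s];
    if (deg[idx] < 3 || cluster[idx]) continue;
    ++ncl;
    std::queue<R_xlen_t> q;
    q.push(idx);
    cluster[idx] = ncl;
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % n1), j = (int)((cur / n1) % n2), k = (int)(cur / plane);
      for (int t = 0; t < NB; ++t) {
        int ii = i + OFF[t][0], jj = j + OFF[t][1], kk = k + OFF[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
        R_xlen_t nb = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * plane;
        if (deg[nb] >= 3 && !cluster[nb]) { cluster[nb] = ncl; q.push(nb); }
      }
    }
  }

  std::vector<char> visited(N, 0);
  std::vector<std::vector<int> > seg_vox;   // 1-based linear indices
  std::vector<int> end1, end2;

  auto neighbors = [&](R_xlen_t cur, std::vector<R_xlen_t>& out) {
    out.clear();
    int i = (int)(cur % n1), j = (int)((cur / n1) % n2), k = (int)(cur / plane);
    for (int t = 0; t < NB; ++t) {
      int ii = i + OFF[t][0], jj = j + OFF[t][1], kk = k + OFF[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
      R_xlen_t nb = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * plane;
      if (deg[nb] >= 0) out.push_back(nb);
    }
  };

  std::vector<R_xlen_t> nbs;
  // chains seeded at degree-2 voxels
  for (size_t s = 0; s < vox.size(); ++s) {
    R_xlen_t seed = vox[s];
    if (deg[seed] != 2 || visited[seed]) continue;
    std::vector<int> chain;
    chain.push_back((int)(seed + 1));
    visited[seed] = 1;
    int etype[2];
    R_xlen_t term[2];
    neighbors(seed, nbs);
    R_xlen_t start_nb[2] = {nbs[0], nbs[1]};
    bool cycle = false;
    for (int dirn = 0; dirn < 2 && !cycle; ++dirn) {
      R_xlen_t prev = seed, cur = start_nb[dirn];
      while (true) {
        if (cur == seed) { cycle = true; break; }
        if (deg[cur] != 2) { // critical terminus
          etype[dirn] = (deg[cur] >= 3) ? 0 : 1;
          term[dirn] = cur;
          break;
        }
        if (visited[cur]) { // closed back onto this chain (cycle with seed interior)
          cycle = true;
          break;
        }
        visited[cur] = 1;
        if (dirn == 0) chain.push_back((int)(cur + 1));
        else chain.insert(chain.begin(), (int)(cur + 1));
        neighbors(cur, nbs);
        R_xlen_t nxt = prev;
        for (size_t t = 0; t < nbs.size(); ++t)
          if (nbs[t] != prev) { nxt = nbs[t]; break; }
        prev = cur;
        cur = nxt;
      }
    }
    if (cycle) {
      seg_vox.push_back(chain);
      end1.push_back(2); end2.push_back(2);
    } else {
      // include free-end terminus voxels in the segment; clusters excluded
      for (int dirn = 0; dirn < 2; ++dirn) {
        if (etype[dirn] == 1 && !visited[term[dirn]]) {
          visited[term[dirn]] = 1;
          if (dirn == 0) chain.push_back((int)(term[dirn] + 1));
          else chain.insert(chain.begin(), (int)(term[dirn] + 1));
        }
      }
      seg_vox.push_back(chain);
      end1.push_back(etype[1]); end2.push_back(etype[0]);
    }
  }

  // direct adjacencies between critical voxels (no degree-2 interior)
  std::set<std::pair<R_xlen_t, R_xlen_t> > pair_seen;
  std::set<std::pair<int, int> > cluster_pair_seen;
  for (size_t s = 0; s < vox.size(); ++s) {
    R_xlen_t a = vox[s];
    if (deg[a] < 1 || deg[a] == 2) continue;
    neighbors(a, nbs);
    for (size_t t = 0; t < nbs.size(); ++t) {
      R_xlen_t b = nbs[t];
      if (deg[b] == 2 || deg[b] < 1) continue;
      bool a_end = deg[a] == 1, b_end = deg[b] == 1;
      if (a_end && b_end) { // isolated two-voxel vessel
        if (visited[a] || visited[b]) continue;
        std::pair<R_xlen_t, R_xlen_t> key(std::min(a, b), std::max(a, b));
        if (pair_seen.count(key)) continue;
        pair_seen.insert(key);
        std::vector<int> chain;
        chain.push_back((int)(key.first + 1));
        chain.push_back((int)(key.second + 1));
        visited[a] = visited[b] = 1;
        seg_vox.push_back(chain);
        end1.push_back(1); end2.push_back(1);
      } else if (a_end && !b_end) { // one-voxel spur off a node
        if (visited[a]) continue;
        visited[a] = 1;
        std::vector<int> chain(1, (int)(a + 1));
        seg_vox.push_back(chain);
        end1.push_back(1); end2.push_back(0);
      } else if (!a_end && !b_end) { // two node clusters touching
        int ca = cluster[a], cb = cluster[b];
        if (ca == cb) continue;
        std::pair<int, int> key(std::min(ca, cb), std::max(ca, cb));
        if (cluster_pair_seen.count(key)) continue;
        cluster_pair_seen.insert(key);
        // keep the two touching node voxels so the segment has a diameter
        std::vector<int> chain;
        chain.push_back((int)(a + 1));
        chain.push_back((int)(b + 1));
        seg_vox.push_back(chain);
        end1.push_back(0); end2.push_back(0);
      }
    }
  }

  // isolated single voxels
  for (size_t s = 0; s < vox.size(); ++s) {
    R_xlen_t a = vox[s];
    if (deg[a] == 0 && !visited[a]) {
      visited[a] = 1;
      seg_vox.push_back(std::vector<int>(1, (int)(a + 1)));
      end1.push_back(3); end2.push_back(3);
    }
  }

  int nseg = (int)seg_vox.size();
  List voxlist(nseg);
  IntegerVector e1(nseg), e2(nseg), nint(nseg);
  for (int s = 0; s < nseg; ++s) {
    voxlist[s] = IntegerVector(seg_vox[s].begin(), seg_vox[s].end());
    e1[s] = end1[s]; e2[s] = end2[s];
    nint[s] = (int)seg_vox[s].size();
  }
  IntegerVector degree_out(N, NA_INTEGER);
  for (size_t s = 0; s < vox.size(); ++s) degree_out[vox[s]] = deg[vox[s]];
  IntegerVector cluster_out(N);
  for (R_xlen_t i = 0; i < N; ++i) cluster_out[i] = cluster[i];
  return List::create(_["voxels"] = voxlist, _["end1"] = e1, _["end2"] = e2,
                      _["n_vox"] = nint, _["degree"] = degree_out,
                      _["n_node_clusters"] = ncl, _["cluster"] = cluster_out);
}

// Multi-source BFS label propagation (26-connectivity) from labelled seed
// voxels through a foreground mask; returns a label per voxel (0 outside /
// unreached). Used to assign every structure voxel to its geodesically
// nearest skeleton segment.
// [[Rcpp::export]]
IntegerVector propagate_labels_cpp(LogicalVector mask, IntegerVector dims,
                                   IntegerVector seed_idx, IntegerVector seed_label) {
  init_off();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  IntegerVector lab(N, 0);
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < seed_idx.size(); ++s) {
    R_xlen_t idx = seed_idx[s] - 1;
    if (idx < 0 || idx >= N || !mask[idx]) continue;
    if (lab[idx] == 0) { lab[idx] = seed_label[s]; q.push(idx); }
  }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = (int)(cur % n1), j = (int)((cur / n1) % n2), k = (int)(cur / plane);
    for (int t = 0; t < NB; ++t) {
      int ii = i + OFF[t][0], jj = j + OFF[t][1], kk = k + OFF[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
      R_xlen_t nb = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * plane;
      if (mask[nb] && lab[nb] == 0) { lab[nb] = lab[cur]; q.push(nb); }
    }
  }
  return lab;
}
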