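name: B
bounds:
- -0.2
- 8.2
- -0.2
- 4.7
obstacles:
- x:
  - -0.1
  - 0.0
  - 0.0
  - -0.1
  'y':
  - -0.1
  - -0.1
  - 4.6
  - 4.6
- x:
  - -0.1
  - 8.1
  - 8.1
  - -0.1
  'y':
  - 4.5
  - 4.5
  - 4.6
  - 4.6
- x:
  - -0.1
  - 8.1
  - 8.1
  - -0.1
  'y':
  - -0.1
  - -0.1
  - 0.0
  - 0.0
- x:
  - 8.0
  - 8.1
  - 8.1
  - 8.0
  'y':
  - -0.1
  - -0.1
  - 4.6
  - 4.6
- x:
  - 4.0
  - 4.1
  - 4.1
  - 4.0
  'y':
  - -0.1
  - -0.1
  - 1.6
  - 1.6
- x:
  - 4.0
  - 4.1
  - 4.1
  - 4.0
  'y':
  - 2.4
  - 2.4
  - 4.6
  - 4.6
- x:
  - 0.1
  - 0.8
  - 0.8
  - 0.1
  'y':
  - 3.7
  - 3.7
  - 4.4
  - 4.4
- x:
  - 6.6
  - 7.0
  - 7.0
  - 6.6
  'y':
  - 0.2
  - 0.2
  - 0.6
  - 0.6
doorways:
  x: 4.05
  'y': 2.0
  width: 0.8
  normal_theta: 0.0
objects:
- id: 1
  class: person
  x: 3.0
  'y': 1.4
  theta: 0.0
  width: 0.5
  depth: 0.5
  height: 1.7
  z_base: 0.0
  shape: cylinder
  vx: 0.0
  vy: 0.0
  dynamic: yes
  solid: yes
- id: 2
  class: chair
  x: 3.1
  'y': 4.1
  theta: -1.5707963
  width: 0.6
  depth: 0.42
  height: 0.9
  z_base: 0.0
  shape: box
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: yes
- id: 3
  class: chair
  x: 0.3
  'y': 2.0
  theta: 0.0
  width: 0.6
  depth: 0.42
  height: 0.9
  z_base: 0.0
  shape: box
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: yes
- id: 4
  class: opened_door
  x: 4.05
  'y': 2.0
  theta: 0.0
  width: 0.8
  depth: 0.1
  height: 2.0
  z_base: 0.0
  shape: door
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: no
- id: 5
  class: desk
  x: 5.6
  'y': 3.7
  theta: -1.5707963
  width: 1.2
  depth: 0.6
  height: 0.75
  z_base: 0.0
  shape: box
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: yes
- id: 6
  class: bottle
  x: 5.55
  'y': 3.5
  theta: 0.0
  width: 0.06
  depth: 0.06
  height: 0.25
  z_base: 0.75
  shape: cylinder
  vx: 0.0
  vy: 0.0
  dynamic: no
  solid: no
start_pose:
- 1.4
- 1.3
- 0.0
tasks:
- step: 1
  mode: auto
  action: goto
  target_class: person
- step: 2
  mode: none
  action: converse
- step: 3
  mode: auto
  action: goto
  target_class: chair
- step: 4
  mode: command
  action: rotate
  command: rotate_right
  amount: 1.5707963
  target_heading: -0.57
- step: 5
  mode: auto
  action: pass_door
  target_class: opened_door
- step: 6
  mode: command
  action: rotate
  command: rotate_left
  amount: 1.5707963
  target_heading: 1.0471976
- step: 7
  mode: auto
  action: goto
  target_class: desk
- step: 8
  mode: auto
  action: pick
  target_class: bottle
- step: 9
  mode: none
  action: drink
walk_to:
- 2.0
- 2.6
walk_speed: 0.5
walk_trigger: 2.5
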